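# Shared constants (this file collates first).

DAYS_PER_YEAR <- 365.25
AGE_MIN_DAYS <- 2192L   # floor(6 * 365.25)
AGE_MAX_DAYS <- 6574L   # floor(18 * 365.25); childhood simulation stops here

SEX_LEVELS <- c("male", "female")
AGE_BANDS <- c("6-10", "11-13", "14-17")
FPL_LEVELS <- c("<100%", "100-199%", "200-399%", ">=400%")
WEIGHT_CLASSES <- c("normal", "overweight", "obese")
EVENT_TYPES <- c("chd", "stroke", "t2d", "cancer")
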