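# Shared fixtures, built in code at test time.

make_conc_df <- function(values = c(1.2, 2.3, 3.4),
                         station = sprintf("S%02d", seq_along(values)),
                         season = "spring_2016_05",
                         matrix = "seawater", metal = "Cu",
                         replicate = 1L) {
  data.frame(station_id = station, longitude = 119.1, latitude = 37.4,
             season = season, matrix = matrix, metal = metal,
             replicate = replicate, value = values)
}

make_tox_df <- function(n = 10, metal = "Cu",
                        groups = rep(c("algae", "fish", "mollusks"),
                                     length.out = n),
                        values = NULL, duration = 10) {
  if (is.null(values)) values <- exp(seq(log(1), log(1000), length.out = n))
  data.frame(species = sprintf("sp_%02d", seq_len(n)),
             functional_group = groups, metal = metal, endpoint = "NOEC",
             duration_days = duration, value_ugL = values)
}

# random log-logistic pair on realistic concentration scales
random_dist_pair <- function() {
  ssd <- risk_dist("log_logistic",
                   c(alpha = stats::runif(1, 5, 50),
                     beta = stats::runif(1, 1, 4)))
  expo <- risk_dist("log_logistic",
                    c(alpha = stats::runif(1, 0.5, 20),
                      beta = stats::runif(1, 2, 10)))
  list(ssd = ssd, exposure = expo)
}
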