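# shared fixtures, built in code at test time

study_weather <- function(seed = 1, n_days = 170) {
  generate_weather(38.9, as.Date("2021-04-20"), n_days, seed = seed)
}

study_sowing <- as.Date("2021-04-25")

study_stage_dates <- as.Date(c("2021-06-22", "2021-08-06", "2021-09-03"))

# truth LAI at the three observation stages for a parameter set
stage_lai <- function(params, weather = study_weather()) {
  s <- suppressWarnings(simulate_crop(params, weather, study_sowing))
  s$trajectory$LAI[match(study_stage_dates, s$trajectory$date)]
}

write_weather_csv <- function(w, path, drop_radiation = FALSE) {
  if (drop_radiation) w$radiation <- NULL
  w$radiation_derived <- NULL
  utils::write.csv(w, path, row.names = FALSE)
  path
}
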