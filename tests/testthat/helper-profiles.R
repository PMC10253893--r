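# fixture builders used across test files

make_profile <- function(time, conc, blq = NULL, route = "iv",
                         species = "mouse", lloq = 0.05, dose = 7500,
                         replicate = 1L, id = "s1") {
  pk_profile(id, species, route, time = time, conc = conc, blq = blq,
             lloq = lloq, dose = dose, dose_unit = "ng", replicate = replicate)
}

# monoexponential profile C0 * exp(-ke t), t in hours
mono_profile <- function(c0 = 100, ke = 0.5, times = seq(0.1, 10, by = 0.5), ...) {
  make_profile(times, c0 * exp(-ke * times), ...)
}

# the acute mouse sampling grid (hours)
mouse_grid <- c(c(1, 5, 10, 15, 30, 45) / 60, 1, 2, 3, 6, 24)

# write a minimal long-format profile file, return its path
write_profile_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

profile_header <- paste("id", "species", "route", "dose", "time",
                        "concentration", "replicate", "lloq", sep = "\t")

profile_row <- function(id = "h1", species = "human", route = "oral",
                        dose = 15, time, conc, replicate = 1, lloq = 0.05) {
  paste(id, species, route, dose, time, conc, replicate, lloq, sep = "\t")
}

# local maxima (indices) of a numeric vector
local_maxima <- function(x) {
  d <- diff(x)
  which(d[-1] < 0 & d[-length(d)] >= 0) + 1L
}
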