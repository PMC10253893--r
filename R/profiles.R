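# Data model and I/O for concentration-time data.
#
# Internal conventions (documented in the vignette):
#   time           hours (minutes accepted on input and converted)
#   concentration  ng/mL
#   dose           ng (mg/ug accepted on input and converted)

#' Concentration-time profile
#'
#' The basic currency of the package: one subject's (or animal's) measured
#' blood concentrations over time for a single route of administration.
#' Censored observations (below the lower limit of quantification, LLOQ) are
#' carried as a logical flag with `NA` concentration so that the censoring
#' rule is applied explicitly by [censor_blq()], never silently.
#'
#' @param subject_id Identifier (coerced to character).
#' @param species `"human"` or `"mouse"`.
#' @param route One of `"iv"`, `"sc"`, `"ip"`, `"oral"`, `"minipump"`.
#' @param time Strictly increasing sampling times.
#' @param conc Concentrations in ng/mL; must be `NA` where `blq` is `TRUE`
#'   and finite, non-negative elsewhere.
#' @param blq Logical vector flagging censored (below-LLOQ) points.
#' @param lloq Lower limit of quantification in ng/mL (> 0).
#' @param dose Administered dose (total daily rate for minipumps).
#' @param dose_unit Unit of `dose`: `"ng"`, `"ug"` or `"mg"`.
#' @param dose_per_kg Dose normalised to body weight, mg/kg (optional).
#' @param replicate Replicate index for duplicate microsampling.
#' @param time_unit Unit of `time`: `"h"` (default) or `"min"`.
#'
#' @return An object of class `pk_profile`: a list with elements
#'   `subject_id`, `species`, `route`, `time` (hours), `conc` (ng/mL),
#'   `blq`, `lloq`, `dose_ng`, `dose_per_kg`, `replicate`.
#'
#' @examples
#' pk_profile("m1", "mouse", "iv", time = c(1, 5, 10) / 60,
#'            conc = c(250, 180, 120), lloq = 0.05,
#'            dose = 7.5, dose_unit = "ug", dose_per_kg = 0.3)
#' @export
pk_profile <- function(subject_id, species = c("human", "mouse"),
                       route = c("iv", "sc", "ip", "oral", "minipump"),
                       time, conc, blq = NULL, lloq, dose,
                       dose_unit = c("ng", "ug", "mg"),
                       dose_per_kg = NA_real_, replicate = 1L,
                       time_unit = c("h", "min")) {
  species <- match.arg(species)
  route <- match.arg(route)
  dose_unit <- match.arg(dose_unit)
  time_unit <- match.arg(time_unit)
  time <- as.numeric(time)
  if (time_unit == "min") time <- time / 60
  conc <- as.numeric(conc)
  if (is.null(blq)) blq <- is.na(conc)
  blq <- as.logical(blq)
  if (length(conc) != length(time) || length(blq) != length(time)) {
    stop("time, conc and blq must have equal length", call. = FALSE)
  }
  if (length(time) == 0L) stop("profile must contain at least one point", call. = FALSE)
  if (anyNA(time) || any(diff(time) <= 0)) {
    stop("times must be non-missing and strictly increasing", call. = FALSE)
  }
  bad <- !blq & (!is.finite(conc) | conc < 0)
  if (any(bad)) {
    stop("uncensored concentrations must be finite and >= 0 (offending index ",
         which(bad)[1L], ")", call. = FALSE)
  }
  conc[blq] <- NA_real_
  lloq <- as.numeric(lloq)
  if (length(lloq) != 1L || !is.finite(lloq) || lloq <= 0) {
    stop("lloq must be a single positive number", call. = FALSE)
  }
  dose_ng <- as.numeric(dose) * switch(dose_unit, ng = 1, ug = 1e3, mg = 1e6)
  if (length(dose_ng) != 1L || !is.finite(dose_ng) || dose_ng <= 0) {
    stop("dose must be a single positive number", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), species = species,
         route = route, time = time, conc = conc, blq = blq, lloq = lloq,
         dose_ng = dose_ng, dose_per_kg = as.numeric(dose_per_kg),
         replicate = as.integer(replicate)),
    class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("<pk_profile> %s %s %s | dose %.4g ng | %d points (%.3g-%.3g h) | %d BLQ | LLOQ %.3g ng/mL\n",
              x$subject_id, x$species, x$route, x$dose_ng, length(x$time),
              min(x$time), max(x$time), sum(x$blq), x$lloq))
  invisible(x)
}

#' @export
as.data.frame.pk_profile <- function(x, ...) {
  data.frame(id = x$subject_id, species = x$species, route = x$route,
             dose = x$dose_ng, dose_unit = "ng",
             dose_per_kg = x$dose_per_kg, time = x$time, time_unit = "h",
             concentration = x$conc, blq = x$blq,
             replicate = x$replicate, lloq = x$lloq,
             stringsAsFactors = FALSE)
}

#' Dosing regimen
#'
#' Describes single, repeated or continuous (zero-order infusion)
#' administration: a set of dose events plus the dosing interval and, for
#' osmotic minipumps, the constant release rate.
#'
#' @param amount Dose amount per event, in `dose_unit`.
#' @param route Administration route.
#' @param dose_unit Unit of `amount`.
#' @param start_time First dose time (h).
#' @param tau Dosing interval in hours; 0 for a single dose.
#' @param n_doses Number of doses.
#' @param infusion_rate Zero-order release rate in ng/day (minipump only).
#' @param infusion_duration Length of the infusion in hours (minipump only).
#'
#' @return An object of class `dosing_regimen`.
#' @export
dosing_regimen <- function(amount, route = c("iv", "sc", "ip", "oral", "minipump"),
                           dose_unit = c("ng", "ug", "mg"), start_time = 0,
                           tau = 0, n_doses = 1L, infusion_rate = NULL,
                           infusion_duration = NULL) {
  route <- match.arg(route)
  dose_unit <- match.arg(dose_unit)
  amount_ng <- as.numeric(amount) * switch(dose_unit, ng = 1, ug = 1e3, mg = 1e6)
  n_doses <- as.integer(n_doses)
  if (any(amount_ng <= 0)) stop("dose amounts must be positive", call. = FALSE)
  if (n_doses > 1L && tau <= 0) {
    stop("tau must be > 0 when n_doses > 1", call. = FALSE)
  }
  if (route == "minipump") {
    if (is.null(infusion_rate) || infusion_rate <= 0) {
      stop("minipump regimens require infusion_rate > 0 (ng/day)", call. = FALSE)
    }
  } else if (!is.null(infusion_rate)) {
    stop("infusion_rate is only meaningful for route = 'minipump'", call. = FALSE)
  }
  events <- data.frame(amount_ng = amount_ng, route = route,
                       start_time = start_time + tau * (seq_len(n_doses) - 1L))
  structure(list(events = events, tau = as.numeric(tau), n_doses = n_doses,
                 infusion_rate = if (is.null(infusion_rate)) NA_real_ else as.numeric(infusion_rate),
                 infusion_duration = if (is.null(infusion_duration)) NA_real_ else as.numeric(infusion_duration)),
            class = "dosing_regimen")
}

#' @export
print.dosing_regimen <- function(x, ...) {
  if (x$events$route[1L] == "minipump") {
    cat(sprintf("<dosing_regimen> minipump %.4g ng/day for %.3g h\n",
                x$infusion_rate, x$infusion_duration))
  } else {
    cat(sprintf("<dosing_regimen> %s %.4g ng x %d, tau = %g h\n",
                x$events$route[1L], x$events$amount_ng[1L], x$n_doses, x$tau))
  }
  invisible(x)
}

# columns required in the delimited long format
.pk_required_cols <- c("id", "species", "route", "dose", "time",
                       "concentration", "replicate", "lloq")
.pk_blq_tokens <- c("<LLOQ", "<lloq", "BLQ", "blq")

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read concentration-time profiles from a delimited text file
#'
#' Reads the package's long format (one row per measurement) from a tab- or
#' comma-separated file and returns one [pk_profile()] per
#' id x route x dose x replicate combination, replicate tags retained (use
#' [average_replicates()] to collapse duplicates). Censored measurements are
#' written as the token `"<LLOQ"` (or `"BLQ"`) in the concentration column.
#'
#' Required columns: `id`, `species`, `route`, `dose`, `time`,
#' `concentration`, `replicate`, `lloq`. Optional columns: `dose_unit`
#' (default mg for human rows, ug for mouse rows), `time_unit` (`"h"`,
#' default, or `"min"`), `dose_per_kg`.
#'
#' @param path Path to the file.
#' @param sep Field separator; by default sniffed from the header line
#'   (tab if present, else comma).
#' @return A list of `pk_profile` objects.
#' @export
read_pk_profiles <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, quote = "\"",
                           comment.char = "")
  missing_cols <- setdiff(.pk_required_cols, names(raw))
  if (length(missing_cols)) {
    stop("format error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0L) stop("format error: file contains no data rows", call. = FALSE)
  rowno <- seq_len(n) + 1L  # file line numbers (header is line 1)

  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !(raw[[col]] %in% c("NA", ""))
    if (any(bad)) {
      stop(sprintf("format error: non-numeric '%s' value '%s' at line %d",
                   col, raw[[col]][which(bad)[1L]], rowno[which(bad)[1L]]),
           call. = FALSE)
    }
    v
  }

  conc_chr <- trimws(raw$concentration)
  blq <- conc_chr %in% .pk_blq_tokens
  conc <- rep(NA_real_, n)
  conc_num <- suppressWarnings(as.numeric(conc_chr))
  bad <- !blq & is.na(conc_num)
  if (any(bad)) {
    stop(sprintf("format error: concentration '%s' at line %d is neither numeric nor a censoring token",
                 conc_chr[which(bad)[1L]], rowno[which(bad)[1L]]), call. = FALSE)
  }
  conc[!blq] <- conc_num[!blq]

  time <- parse_num("time")
  dose <- parse_num("dose")
  lloq <- parse_num("lloq")
  dose_per_kg <- if ("dose_per_kg" %in% names(raw)) parse_num("dose_per_kg") else rep(NA_real_, n)
  time_unit <- if ("time_unit" %in% names(raw)) raw$time_unit else rep("h", n)
  dose_unit <- if ("dose_unit" %in% names(raw)) {
    raw$dose_unit
  } else {
    ifelse(raw$species == "human", "mg", "ug")
  }

  key <- paste(raw$id, raw$route, raw$dose, raw$replicate, sep = "\r")
  profiles <- lapply(split(seq_len(n), factor(key, levels = unique(key))), function(idx) {
    t_h <- time[idx] * ifelse(time_unit[idx] == "min", 1 / 60, 1)
    dup <- duplicated(t_h)
    if (any(dup)) {
      stop(sprintf("validation error: duplicate (time, replicate) rows for subject '%s' at line %d",
                   raw$id[idx[1L]], rowno[idx[dup][1L]]), call. = FALSE)
    }
    if (any(diff(t_h) <= 0)) {
      stop(sprintf("validation error: non-monotone time within replicate for subject '%s' (lines %s)",
                   raw$id[idx[1L]], paste(range(rowno[idx]), collapse = "-")),
           call. = FALSE)
    }
    pk_profile(subject_id = raw$id[idx[1L]], species = raw$species[idx[1L]],
               route = raw$route[idx[1L]], time = t_h, conc = conc[idx],
               blq = blq[idx], lloq = lloq[idx][1L], dose = dose[idx][1L],
               dose_unit = dose_unit[idx][1L],
               dose_per_kg = dose_per_kg[idx][1L],
               replicate = as.integer(raw$replicate[idx][1L]))
  })
  names(profiles) <- NULL
  profiles
}

#' Write concentration-time profiles to a delimited text file
#'
#' Inverse of [read_pk_profiles()]: writes the long format with full
#' (17-significant-digit) numeric precision so that a read/write cycle
#' round-trips bit-identically. Censored points are written as `"<LLOQ"`.
#'
#' @param profiles A `pk_profile` or list of them.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_pk_profiles <- function(profiles, path, sep = "\t") {
  if (inherits(profiles, "pk_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(id = p$subject_id, species = p$species, route = p$route,
               dose = .fmt_num(p$dose_ng), dose_unit = "ng",
               dose_per_kg = .fmt_num(p$dose_per_kg),
               time = .fmt_num(p$time), time_unit = "h",
               concentration = ifelse(p$blq, "<LLOQ", .fmt_num(p$conc)),
               replicate = p$replicate, lloq = .fmt_num(p$lloq),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average duplicate replicates of a profile
#'
#' Collapses duplicate microsampling replicates to a single profile by the
#' per-time arithmetic mean of the uncensored replicate values. A time point
#' at which every replicate is censored stays censored. Already-averaged
#' input (a single profile) is returned unchanged, so the operation is
#' idempotent.
#'
#' @param profiles List of `pk_profile` replicates sharing a time grid.
#' @param tol Time-grid alignment tolerance in hours (default 1 minute).
#' @return A single `pk_profile` with `replicate = 1`.
#' @export
average_replicates <- function(profiles, tol = 1 / 60) {
  if (inherits(profiles, "pk_profile")) return(profiles)
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "pk_profile")))
  ref <- profiles[[1L]]
  if (length(profiles) == 1L) return(ref)
  same <- vapply(profiles, function(p) {
    identical(p$species, ref$species) && identical(p$route, ref$route) &&
      isTRUE(all.equal(p$dose_ng, ref$dose_ng))
  }, logical(1))
  if (!all(same)) {
    stop("replicates must share species, route and dose", call. = FALSE)
  }
  aligned <- vapply(profiles, function(p) {
    length(p$time) == length(ref$time) && all(abs(p$time - ref$time) <= tol)
  }, logical(1))
  if (!all(aligned)) {
    stop("alignment error: replicate time grids differ by more than ",
         signif(tol, 3), " h", call. = FALSE)
  }
  cmat <- vapply(profiles, `[[`, numeric(length(ref$time)), "conc")
  cmat <- matrix(cmat, nrow = length(ref$time))
  mean_conc <- rowMeans(cmat, na.rm = TRUE)   # NaN when all replicates censored
  all_blq <- !is.finite(mean_conc)
  mean_conc[all_blq] <- NA_real_
  pk_profile(subject_id = ref$subject_id, species = ref$species,
             route = ref$route, time = ref$time, conc = mean_conc,
             blq = all_blq, lloq = ref$lloq, dose = ref$dose_ng,
             dose_unit = "ng", dose_per_kg = ref$dose_per_kg, replicate = 1L)
}

#' Apply a below-LLOQ censoring rule
#'
#' Standard NCA handling of censored observations. The default rule
#' (`"zero-drop"`) sets censored points before the first quantifiable
#' concentration to zero and excludes censored points at or after the last
#' quantifiable concentration (and any embedded ones) from all downstream
#' computation, so they enter neither the terminal-slope fit nor the AUC.
#' The alternative rule (`"half-lloq"`) imputes LLOQ/2 everywhere.
#'
#' @param profile A `pk_profile`.
#' @param rule `"zero-drop"` (default) or `"half-lloq"`.
#' @return A `pk_profile` with no remaining censored flags.
#' @export
censor_blq <- function(profile, rule = c("zero-drop", "half-lloq")) {
  stopifnot(inherits(profile, "pk_profile"))
  rule <- match.arg(rule)
  if (all(profile$blq)) {
    stop("empty-profile error: every point is below the LLOQ", call. = FALSE)
  }
  if (!any(profile$blq)) return(profile)
  conc <- profile$conc
  blq <- profile$blq
  if (rule == "half-lloq") {
    conc[blq] <- profile$lloq / 2
    keep <- rep(TRUE, length(conc))
  } else {
    first_q <- which(!blq)[1L]
    conc[blq & seq_along(conc) < first_q] <- 0
    keep <- !(blq & seq_along(conc) >= first_q)
  }
  pk_profile(subject_id = profile$subject_id, species = profile$species,
             route = profile$route, time = profile$time[keep],
             conc = conc[keep], blq = rep(FALSE, sum(keep)),
             lloq = profile$lloq, dose = profile$dose_ng, dose_unit = "ng",
             dose_per_kg = profile$dose_per_kg, replicate = profile$replicate)
}

#' Descriptive statistics in the study's reporting convention
#'
#' Arithmetic mean, SD, median, maximum, geometric mean and geometric CV%
#' for a vector of positive values (typically Cmax or AUC across subjects).
#' The geometric mean is `exp(mean(log(x)))` and the geometric CV is
#' `100 * sqrt(exp(var(log(x))) - 1)` with the usual n-1 variance
#' denominator.
#'
#' @param x Numeric vector, `n >= 1`; all values must be positive when
#'   `geometric = TRUE`.
#' @param geometric Compute geometric statistics (default `TRUE`).
#' @return A one-row data.frame with columns `n`, `mean`, `sd`, `median`,
#'   `max`, `geo_mean`, `geo_cv_pct`.
#' @examples
#' pk_summary(c(28.21, 19.22, 26.64))  # mean terminal half-life, 24.69 h
#' @export
pk_summary <- function(x, geometric = TRUE) {
  x <- as.numeric(x)
  if (length(x) < 1L || anyNA(x)) stop("x must be non-missing with n >= 1", call. = FALSE)
  if (geometric && any(x <= 0)) {
    stop("domain error: geometric statistics require all values > 0", call. = FALSE)
  }
  s <- if (length(x) > 1L) stats::sd(x) else 0
  if (geometric) {
    lx <- log(x)
    gm <- exp(mean(lx))
    gcv <- if (length(x) > 1L) 100 * sqrt(exp(stats::var(lx)) - 1) else 0
  } else {
    gm <- NA_real_
    gcv <- NA_real_
  }
  data.frame(n = length(x), mean = mean(x), sd = s, median = stats::median(x),
             max = max(x), geo_mean = gm, geo_cv_pct = gcv)
}
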