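#' Built-in internal reference standards
#'
#' 2C nuclear DNA contents (pg per nucleus) of the co-prepared standards
#' commonly used to calibrate cytometric measurements: chicken erythrocyte
#' nuclei 2.50 pg, human leukocytes 7.00 pg, rainbow trout erythrocytes
#' 5.2 pg, fruit fly 0.40 pg.
#'
#' @param name one of `"chicken"`, `"human"`, `"trout"`, `"fruit_fly"`, or a
#'   custom name with `two_C_pg` supplied.
#' @param two_C_pg 2C DNA content in picograms (> 0); overrides built-ins.
#' @return a `reference_standard` list with `name` and `two_C_pg`.
#' @export
reference_standard <- function(name, two_C_pg = NULL) {
  builtins <- c(chicken = 2.50, human = 7.00, trout = 5.2, fruit_fly = 0.40)
  if (is.null(two_C_pg)) {
    if (!name %in% names(builtins)) {
      stop("unknown standard '", name, "'; supply two_C_pg")
    }
    two_C_pg <- builtins[[name]]
  }
  stopifnot(two_C_pg > 0)
  structure(list(name = name, two_C_pg = two_C_pg),
            class = "reference_standard")
}

#' Flow-cytometric nuclear DNA content
#'
#' `pg = mean_FL * standard 2C pg / standard_FL`: the sample's mean
#' fluorescence channel value scaled by the internal standard of known DNA
#' content measured in the same run.
#'
#' @param mean_FL mean fluorescence of the sample nuclei (arbitrary channel
#'   units, > 0).
#' @param standard_FL mean fluorescence of the reference standard (> 0).
#' @param standard a [reference_standard()] (default chicken, 2.50 pg).
#' @return 2C DNA content in pg.
#' @export
fcm_dna_content <- function(mean_FL, standard_FL,
                            standard = reference_standard("chicken")) {
  if (any(c(mean_FL, standard_FL) <= 0)) {
    stop("fluorescence values must be positive")
  }
  mean_FL * standard$two_C_pg / standard_FL
}

#' Feulgen-densitometric nuclear DNA content
#'
#' Converts per-nucleus integrated optical densities (IOD) to picograms
#' against a standard: `pg_c = (pg_s / IOD_s) * IOD_c`. The coefficient of
#' variation is computed on the raw IOD values (not on converted pg).
#'
#' @param iod_values per-nucleus IODs of the specimen (> 0, >= 1 nucleus).
#' @param standard_mean_iod mean IOD of the reference standard (> 0).
#' @param standard a [reference_standard()] (default chicken/hen, 2.50 pg).
#' @return list: `pg_per_nucleus` (vector), `mean_pg`, `sem_pg` (sample SD /
#'   sqrt(n), NA for n = 1), `cv_pct` (sample SD of IOD / mean IOD * 100),
#'   `n`.
#' @export
fiad_dna_content <- function(iod_values, standard_mean_iod,
                             standard = reference_standard("chicken")) {
  if (length(iod_values) < 1L) stop("at least one nucleus is required")
  if (any(iod_values <= 0) || standard_mean_iod <= 0) {
    stop("IOD values must be positive")
  }
  pg <- (standard$two_C_pg / standard_mean_iod) * iod_values
  n <- length(iod_values)
  list(pg_per_nucleus = pg,
       mean_pg = mean(pg),
       sem_pg = if (n > 1L) sd(pg) / sqrt(n) else NA_real_,
       cv_pct = if (n > 1L) 100 * sd(iod_values) / mean(iod_values)
                else NA_real_,
       n = n)
}

#' Calibration curve of standards: pg on IOD
#'
#' Ordinary least squares of known DNA amounts on measured mean IODs across
#' reference standards; quantitative Feulgen staining shows an r-squared
#' near 1 over the standards' range.
#'
#' @param mean_iod mean IOD per standard (>= 2 distinct values).
#' @param known_pg known 2C pg per standard.
#' @return list: `slope`, `intercept`, `r_squared`.
#' @export
calibration_curve <- function(mean_iod, known_pg) {
  stopifnot(length(mean_iod) == length(known_pg), length(mean_iod) >= 2L)
  if (length(unique(mean_iod)) < 2L) {
    stop("standards have coincident IODs; cannot fit a calibration line")
  }
  fit <- stats::lm(known_pg ~ mean_iod)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((known_pg - mean(known_pg))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2)
}

#' Picogram / gigabase conversion (1 pg DNA = 0.978 Gb)
#'
#' Reported values are conventionally rounded half-away-from-zero to two
#' decimals; set `round_digits = NA` for the exact value.
#'
#' @param pg DNA amount in picograms (>= 0).
#' @param round_digits decimals for the reported value (default 2; `NA` for
#'   exact).
#' @return DNA amount in Gb.
#' @export
pg_to_gb <- function(pg, round_digits = 2) {
  stopifnot(all(pg >= 0))
  gb <- pg * 0.978
  if (is.na(round_digits)) gb else round_half_up(gb, round_digits)
}

#' @rdname pg_to_gb
#' @param gb DNA amount in Gb (>= 0).
#' @export
gb_to_pg <- function(gb, round_digits = 2) {
  stopifnot(all(gb >= 0))
  pg <- gb / 0.978
  if (is.na(round_digits)) pg else round_half_up(pg, round_digits)
}

#' Average estimates over internal standards
#'
#' When a specimen is measured against several internal standards the
#' reported pg value is their arithmetic mean; conversion to Gb happens
#' after averaging.
#'
#' @param values per-standard pg estimates (>= 1).
#' @return mean pg.
#' @export
combine_standards <- function(values) {
  stopifnot(length(values) >= 1L)
  mean(values)
}

#' Mean and SEM over specimens
#'
#' The unit of replication is the specimen (not the nucleus), avoiding
#' pseudoreplication in cross-group comparisons. Mean is rounded to 2
#' decimals, SEM (sample SD / sqrt(n)) to 3; SEM is `NA` for n = 1.
#'
#' @param values per-specimen pg values.
#' @return list: `mean`, `sem`, `n`.
#' @export
summarize_specimens <- function(values) {
  n <- length(values)
  stopifnot(n >= 1L)
  list(mean = round_half_up(mean(values), 2),
       sem = if (n > 1L) round_half_up(sd(values) / sqrt(n), 3) else NA_real_,
       n = n)
}

#' 2C / 1C conversions
#'
#' The haploid (1C) amount is half the somatic diploid (2C) amount — valid
#' only in the absence of chromatin diminution; conversely a gametic 1C
#' measurement doubles to a derived 2C value.
#'
#' @param two_C_pg 2C amount (> 0).
#' @return 1C amount.
#' @export
derive_1C <- function(two_C_pg) {
  stopifnot(all(two_C_pg > 0))
  two_C_pg / 2
}

#' @rdname derive_1C
#' @param one_C_pg gametic 1C amount (> 0).
#' @export
derive_2C_from_gamete <- function(one_C_pg) {
  stopifnot(all(one_C_pg > 0))
  one_C_pg * 2
}

#' Build a per-specimen cytometry record
#'
#' Combines per-standard 2C pg estimates into the reported record: combined
#' pg (mean over standards), Gb (rounded after averaging), and the 1C
#' values.
#'
#' @param specimen specimen label.
#' @param method `"FCM"` or `"FIAD"`.
#' @param pg_by_standard named numeric vector of per-standard 2C pg values.
#' @param cv_pct coefficient of variation of the raw FL/IOD values (%).
#' @param sem_pg standard error of the mean (pg).
#' @param n number of nuclei (or samples) measured.
#' @return a `cytometry_record` list.
#' @export
cytometry_record <- function(specimen, method = c("FCM", "FIAD"),
                             pg_by_standard, cv_pct = NA_real_,
                             sem_pg = NA_real_, n = NA_integer_) {
  method <- match.arg(method)
  two_c <- combine_standards(pg_by_standard)
  structure(list(specimen = specimen, method = method,
                 pg_by_standard = pg_by_standard,
                 two_C_pg = two_c,
                 two_C_gb = pg_to_gb(two_c),
                 one_C_pg = derive_1C(two_c),
                 one_C_gb = pg_to_gb(derive_1C(two_c)),
                 cv_pct = cv_pct, sem_pg = sem_pg, n = n),
            class = "cytometry_record")
}

#' Convert a tidy per-measurement table into cytometry records
#'
#' Input layout (CSV-friendly), one row per nucleus (FIAD) or per sample
#' summary (FCM): `specimen`, `method` (FCM|FIAD), `value` (FL or IOD),
#' `value_type` (FL|IOD), `standard_name`, `standard_value` (the standard's
#' FL or mean IOD in the same units), and optionally `standard_pg`
#' overriding the built-in 2C content.
#'
#' @param df data.frame in the layout above.
#' @return data.frame, one row per specimen x standard:
#'   `specimen, method, standard, n, mean_pg, sem_pg, cv_pct, mean_gb`.
#' @export
cytometry_table <- function(df) {
  need <- c("specimen", "method", "value", "value_type", "standard_name",
            "standard_value")
  stopifnot(all(need %in% names(df)))
  out <- list()
  for (key in unique(paste(df$specimen, df$standard_name, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- df[df$specimen == parts[1L] & df$standard_name == parts[2L], ]
    std <- if ("standard_pg" %in% names(sub) && !is.na(sub$standard_pg[1L])) {
      reference_standard(parts[2L], sub$standard_pg[1L])
    } else {
      reference_standard(parts[2L])
    }
    if (toupper(sub$method[1L]) == "FIAD") {
      res <- fiad_dna_content(sub$value, sub$standard_value[1L], std)
      row <- data.frame(specimen = parts[1L], method = "FIAD",
                        standard = parts[2L], n = res$n,
                        mean_pg = res$mean_pg, sem_pg = res$sem_pg,
                        cv_pct = res$cv_pct)
    } else {
      pg <- fcm_dna_content(sub$value, sub$standard_value, std)
      n <- length(pg)
      row <- data.frame(specimen = parts[1L], method = "FCM",
                        standard = parts[2L], n = n,
                        mean_pg = mean(pg),
                        sem_pg = if (n > 1L) sd(pg) / sqrt(n) else NA_real_,
                        cv_pct = if (n > 1L) 100 * sd(sub$value) /
                                   mean(sub$value) else NA_real_)
    }
    row$mean_gb <- pg_to_gb(row$mean_pg)
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
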