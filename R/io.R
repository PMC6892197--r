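#' Write a cohort to CSV
#'
#' Comma-delimited UTF-8 with a mandatory header. Two encodings are
#' distinguished among unobserved values: *undefined* quantities (outcomes
#' or attendance of participants who died before follow-up) are written as
#' empty fields, while *missing* outcomes of surviving non-attenders are
#' written as the literal token `NA`. The truth view writes all generator
#' columns (`id,V1,V2,U,D,A,Z0,Z1,stratum,Y0,Y1,Z,R,Y_obs`); the observed
#' view writes `id,V1,V2,A,Z,R,Y_obs`.
#'
#' @param cohort A `sace_cohort` (truth or observed view).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  view <- attr(cohort, "view")
  if (is.null(view)) view <- if ("stratum" %in% names(cohort)) "truth" else "observed"
  df <- as.data.frame(cohort)
  enc <- function(x, undefined, missing = NULL) {
    out <- as.character(x)
    if (!is.null(missing)) out[missing] <- "NA"
    out[undefined] <- ""
    out[is.na(out)] <- ""  # nothing should remain, defensive
    out
  }
  dead <- df$Z == 0L
  df$R <- enc(df$R, undefined = dead)
  df$Y_obs <- enc(df$Y_obs, undefined = dead,
                  missing = !dead & !is.na(df$R) & df$R == "0")
  if (view == "truth") {
    df$Y0 <- enc(df$Y0, undefined = df$Z0 == 0L)
    df$Y1 <- enc(df$Y1, undefined = df$Z1 == 0L)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Reads a cohort written by [write_cohort()] (or assembled externally in
#' the same layout), restoring the undefined/missing distinction and
#' validating integrity: binary columns must be 0/1, `Y_obs` must be absent
#' (empty) for non-survivors and `R` absent for the dead. Reading a truth
#' file with `view = "observed"` drops the hidden columns with a message.
#'
#' @param path CSV file path.
#' @param view `"observed"` or `"truth"`; the requested analyst view.
#' @return A `sace_cohort` data frame of the requested view.
#' @export
read_cohort <- function(path, view = c("observed", "truth")) {
  view <- match.arg(view)
  # keep the literal "NA" token and empty fields distinguishable
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(0))
  truth_cols <- c("id", "V1", "V2", "U", "D", "A", "Z0", "Z1", "stratum",
                  "Y0", "Y1", "Z", "R", "Y_obs")
  obs_cols <- c("id", "V1", "V2", "A", "Z", "R", "Y_obs")
  need <- if (view == "truth") truth_cols else obs_cols
  if (!all(need %in% names(df)))
    stop("cohort file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), truth_cols)
  if (length(extra))
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "),
            call. = FALSE)
  if (view == "observed" && "stratum" %in% names(df))
    message("truth file read as observed view: hidden columns dropped")
  df <- df[, intersect(need, names(df))]

  int_col <- function(nm, allow_empty = FALSE, allow_na = FALSE) {
    x <- df[[nm]]
    bad <- !(x %in% c("0", "1", if (allow_empty) "", if (allow_na) "NA"))
    if (any(bad))
      stop(sprintf("malformed binary column '%s' at row %d (value '%s')",
                   nm, which(bad)[1], x[which(bad)[1]]), call. = FALSE)
    suppressWarnings(as.integer(ifelse(x %in% c("", "NA"), NA, x)))
  }
  out <- data.frame(id = as.integer(df$id), V1 = int_col("V1"),
                    V2 = as.numeric(df$V2))
  if (view == "truth") { out$U <- int_col("U"); out$D <- int_col("D") }
  out$A <- int_col("A")
  if (view == "truth") {
    out$Z0 <- int_col("Z0"); out$Z1 <- int_col("Z1")
    if (!all(df$stratum %in% c("AS", "CS", "DS", "NS")))
      stop("malformed 'stratum' column", call. = FALSE)
    out$stratum <- factor(df$stratum, levels = c("AS", "CS", "DS", "NS"))
    out$Y0 <- int_col("Y0", allow_empty = TRUE)
    out$Y1 <- int_col("Y1", allow_empty = TRUE)
  }
  out$Z <- int_col("Z")
  out$R <- int_col("R", allow_empty = TRUE)
  out$Y_obs <- int_col("Y_obs", allow_empty = TRUE, allow_na = TRUE)

  dead <- out$Z == 0L
  if (any(dead & df$Y_obs != ""))
    stop(sprintf("integrity error: Y_obs present for non-survivor at row %d",
                 which(dead & df$Y_obs != "")[1]), call. = FALSE)
  if (any(dead & df$R != ""))
    stop(sprintf("integrity error: R present for non-survivor at row %d",
                 which(dead & df$R != "")[1]), call. = FALSE)
  if (any(!dead & is.na(out$R)))
    stop("integrity error: attendance missing for a survivor", call. = FALSE)
  if (view == "truth") {
    if (any(out$Z0 == 0L & df$Y0 != "") || any(out$Z1 == 0L & df$Y1 != ""))
      stop("integrity error: potential outcome present where potential survival is 0",
           call. = FALSE)
  }
  class(out) <- c("sace_cohort", "data.frame")
  attr(out, "view") <- view
  out
}

#' Parse a scenario configuration file
#'
#' Reads a JSON or YAML file (by extension) describing one scenario and
#' returns a validated [scenario_config()]. Unknown keys are rejected with
#' a message naming them. Odds-ratio-style inputs (`alpha_UZ`, `beta_UY`)
#' may be written as the strings `"ln(x)"` to avoid transcribing logs;
#' values outside the canonical grid are accepted with a warning (custom
#' scenario).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `sace_scenario` object.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stop("config must be JSON or YAML", call. = FALSE)

  known <- c("alpha_UZ", "beta_UY", "monotonicity", "n_participants", "n_reps",
             "target_sace_or", "base_seed", "covariates", "exposure_coefs",
             "survival_coefs", "outcome_coefs", "attendance_coefs",
             "survival_coupling")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in c("alpha_UZ", "beta_UY"))
    if (!is.null(raw[[k]])) raw[[k]] <- .parse_lor(raw[[k]], k)
  for (k in c("exposure_coefs", "survival_coefs", "outcome_coefs", "attendance_coefs"))
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  if (!is.null(raw$n_reps) && raw$n_reps <= 0)
    stop("'n_reps' must be positive", call. = FALSE)
  cfg <- do.call(scenario_config, raw)
  grid_a <- c(log(0.5), log(2)); grid_b <- c(log(0.5), 0, log(2))
  if (min(abs(cfg$alpha_UZ - grid_a)) > 1e-9 || min(abs(cfg$beta_UY - grid_b)) > 1e-9)
    warning("custom scenario: (alpha_UZ, beta_UY) outside the canonical grid",
            call. = FALSE)
  cfg
}

.parse_lor <- function(x, key) {
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  m <- regmatches(x, regexec("^ln\\(([0-9.eE+-]+)\\)$", x))[[1]]
  if (length(m) == 2L) return(log(as.numeric(m[2])))
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v))
    stop(sprintf("cannot parse '%s' for key '%s' (use a number or \"ln(x)\")",
                 x, key), call. = FALSE)
  v
}

#' Tiny deterministic cohorts for oracle tests
#'
#' Hand-constructed fixtures with exactly known strata counts, 2x2 tables
#' and closed-form estimates:
#' \describe{
#'   \item{`"strata-basic"`}{10 participants with 4 AS, 3 CS, 2 DS, 1 NS by
#'     construction of `(Z0, Z1)`.}
#'   \item{`"logistic-2x2"`}{50 participants forming the exposure-by-outcome
#'     table (10, 20, 15, 5), whose logistic slope is `log(10 * 5 / (20 * 15))`.}
#'   \item{`"tau-3"`}{A truth cohort whose compliant-survivors have outcome
#'     odds 1 and always-survivors odds 1/3 under exposure, so `tau = 3`.}
#' }
#'
#' @param name Fixture name.
#' @return A data frame (a truth-view `sace_cohort` where applicable).
#' @export
make_fixture <- function(name = c("strata-basic", "logistic-2x2", "tau-3")) {
  name <- match.arg(name)
  finish_truth <- function(df) {
    df$id <- seq_len(nrow(df))
    df$stratum <- assign_strata(df$Z0, df$Z1)
    df$Z <- ifelse(df$A == 1L, df$Z1, df$Z0)
    df$R[df$Z == 0L] <- NA_integer_
    df$Y_obs <- ifelse(df$Z == 1L & !is.na(df$R) & df$R == 1L,
                       ifelse(df$A == 1L, df$Y1, df$Y0), NA_integer_)
    df <- df[, c("id", "V1", "V2", "U", "D", "A", "Z0", "Z1", "stratum",
                 "Y0", "Y1", "Z", "R", "Y_obs")]
    class(df) <- c("sace_cohort", "data.frame")
    attr(df, "view") <- "truth"
    df
  }
  if (name == "strata-basic") {
    df <- data.frame(
      V1 = rep(c(0L, 1L), 5), V2 = seq(-5, 4), U = rep(c(0L, 1L), each = 5),
      D = 0L, A = rep(c(0L, 1L), 5),
      Z0 = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L),
      Z1 = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L),
      R = 1L
    )
    df$Y0 <- ifelse(df$Z0 == 1L, rep(c(0L, 1L), 5), NA_integer_)
    df$Y1 <- ifelse(df$Z1 == 1L, rep(c(1L, 0L), 5), NA_integer_)
    return(finish_truth(df))
  }
  if (name == "logistic-2x2") {
    # exposure x outcome: (A=1,Y=1)=10, (A=1,Y=0)=20, (A=0,Y=1)=15, (A=0,Y=0)=5
    return(data.frame(
      A = rep(c(1L, 1L, 0L, 0L), c(10, 20, 15, 5)),
      Y = rep(c(1L, 0L, 1L, 0L), c(10, 20, 15, 5))
    ))
  }
  # tau-3: 4 CS with Y1 = (1,1,0,0) -> odds 1; 4 AS with Y1 = (1,0,0,0) -> odds 1/3
  df <- data.frame(
    V1 = rep(c(0L, 1L), 4), V2 = rep(0, 8), U = 0L, D = 0L,
    A = rep(1L, 8),
    Z0 = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
    Z1 = 1L, R = 1L
  )
  df$Y1 <- c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L)
  df$Y0 <- ifelse(df$Z0 == 1L, c(NA, NA, NA, NA, 0L, 1L, 0L, 0L), NA_integer_)
  finish_truth(df)
}
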