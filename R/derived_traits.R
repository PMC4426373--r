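#' Fulton condition factor
#'
#' K = (W / L^3) x 100,000 with weight in grams and fork length in mm; an
#' index of "plumpness". Non-positive or missing inputs yield `NA` (with a
#' warning for non-positive values).
#'
#' @param weight_g body weight in grams.
#' @param length_mm fork length in millimetres.
#' @return numeric vector of K values.
#' @examples
#' condition_factor(10, 100)  # 1
#' @export
condition_factor <- function(weight_g, length_mm) {
  bad <- (!is.na(weight_g) & weight_g <= 0) |
         (!is.na(length_mm) & length_mm <= 0)
  if (any(bad))
    warning(sum(bad), " non-positive weight/length value(s) set to NA")
  k <- (weight_g / length_mm^3) * 1e5
  k[bad] <- NA_real_
  k
}

#' Instantaneous growth rate
#'
#' IGR = [ln(x2) - ln(x1)] / (t2 - t1) x 100, in percent per day, for body
#' length (mm) or weight (g) measured at times t1 < t2 (days after
#' fertilization).
#'
#' @param x1,x2 size at the start/end of the interval.
#' @param t1,t2 measurement times in days after fertilization.
#' @return numeric vector of growth rates (% per day).
#' @examples
#' instantaneous_growth_rate(1, exp(1), 0, 100)  # 1
#' @export
instantaneous_growth_rate <- function(x1, x2, t1, t2) {
  if (any(t2 <= t1)) stop("t2 must exceed t1 for every interval")
  bad <- (!is.na(x1) & x1 <= 0) | (!is.na(x2) & x2 <= 0)
  x1[bad] <- NA_real_
  x2[bad] <- NA_real_
  (log(x2) - log(x1)) / (t2 - t1) * 100
}

#' Decompose the four-level life-history class into binary traits
#'
#' `LHSmolt`: smolt = 1; mature and parr = 0; indeterminate and missing = NA.
#' `LHMature`: mature = 1; parr, indeterminate and smolt = 0; missing = NA.
#'
#' @param category character vector with levels
#'   `"mature"`, `"parr"`, `"indeterminate"`, `"smolt"` (or `NA`).
#' @return data frame with integer columns `LHSmolt` and `LHMature`.
#' @export
binarize_life_history <- function(category) {
  category <- as.character(category)
  known <- c("mature", "parr", "indeterminate", "smolt")
  bad <- !is.na(category) & !(category %in% known)
  if (any(bad))
    stop("unknown life-history token(s): ",
         paste(unique(category[bad]), collapse = ", "))
  smolt <- ifelse(is.na(category) | category == "indeterminate",
                  NA_integer_, as.integer(category == "smolt"))
  mature <- ifelse(is.na(category), NA_integer_,
                   as.integer(category == "mature"))
  data.frame(LHSmolt = smolt, LHMature = mature)
}

# Nominal sampling ages in days after fertilization. The study reports only
# month labels (12/15/24 mo); 30.44 d/mo is the mean Gregorian month length.
nominal_age_days <- function(months) months * 30.44

#' Append derived phenotypes to a phenotype table
#'
#' Adds condition factors (`mo12Kfact`, `mo15Kfact`, `mo24Kfact`),
#' instantaneous growth rates (`IGRL1`, `IGRW1` over 12-15 mo; `IGRL2`,
#' `IGRW2` over 15-24 mo) and the binary life-history decomposition
#' (`LHSmolt`, `LHMature`). Inputs are never overwritten and the operation is
#' idempotent. Interval lengths use columns `mo12Age`, `mo15Age`, `mo24Age`
#' (days after fertilization) when present, else nominal ages
#' (12/15/24 months at 30.44 d each), recorded in attribute `"age_source"`.
#'
#' @param data data frame with columns `mo12Length`, `mo12Weight`, ...,
#'   `mo24Weight` and optionally `life_history`.
#' @return `data` with derived columns appended.
#' @export
derive_traits <- function(data) {
  stopifnot(is.data.frame(data))
  out <- data
  for (tp in c("mo12", "mo15", "mo24")) {
    kf <- paste0(tp, "Kfact")
    wcol <- paste0(tp, "Weight"); lcol <- paste0(tp, "Length")
    if (!kf %in% names(out) && all(c(wcol, lcol) %in% names(out)))
      out[[kf]] <- condition_factor(out[[wcol]], out[[lcol]])
  }
  ages <- lapply(c(12, 15, 24), function(m) {
    col <- sprintf("mo%dAge", m)
    if (col %in% names(out)) out[[col]] else
      rep(nominal_age_days(m), nrow(out))
  })
  age_source <- if (any(sprintf("mo%dAge", c(12, 15, 24)) %in% names(data)))
    "individual" else "nominal"
  igr_spec <- list(
    IGRL1 = c("mo12Length", "mo15Length", 1, 2),
    IGRW1 = c("mo12Weight", "mo15Weight", 1, 2),
    IGRL2 = c("mo15Length", "mo24Length", 2, 3),
    IGRW2 = c("mo15Weight", "mo24Weight", 2, 3))
  for (nm in names(igr_spec)) {
    sp <- igr_spec[[nm]]
    if (!nm %in% names(out) && all(sp[1:2] %in% names(out)))
      out[[nm]] <- instantaneous_growth_rate(
        out[[sp[1]]], out[[sp[2]]],
        ages[[as.integer(sp[3])]], ages[[as.integer(sp[4])]])
  }
  if ("life_history" %in% names(out) &&
      !all(c("LHSmolt", "LHMature") %in% names(out))) {
    bl <- binarize_life_history(out$life_history)
    if (!"LHSmolt" %in% names(out)) out$LHSmolt <- bl$LHSmolt
    if (!"LHMature" %in% names(out)) out$LHMature <- bl$LHMature
  }
  attr(out, "age_source") <- age_source
  out
}

#' Read / write a wide phenotype CSV
#'
#' One row per individual, first column `id`, remaining columns named by the
#' trait abbreviations (mo12Length, ..., LHSmolt, LHMature, AvgPix,
#' CentroidSize, RelW*); missing values empty or "NA".
#'
#' @param path file path.
#' @return data frame of phenotypes.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"id" %in% names(df)) stop("phenotype file must have an 'id' column")
  df$id <- as.character(df$id)
  df
}

#' @rdname read_phenotypes
#' @param data phenotype data frame.
#' @export
write_phenotypes <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
}
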