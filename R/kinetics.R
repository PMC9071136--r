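#' Construct a kinetic fluorescence trace
#'
#' @param time_points ordered time points (minutes).
#' @param rfu numeric matrix of relative fluorescence units, one row per
#'   time point, one column per replicate (a vector is treated as a single
#'   replicate).
#' @param compound,concentration optional metadata (concentration in uM).
#' @return a `kinetic_trace`.
#' @export
kinetic_trace <- function(time_points, rfu, compound = NA_character_,
                          concentration = NA_real_) {
  if (is.vector(rfu)) rfu <- matrix(rfu, ncol = 1)
  stopifnot(nrow(rfu) == length(time_points))
  if (is.unsorted(time_points, strictly = TRUE)) {
    stop("time points must be strictly increasing")
  }
  structure(list(time = as.numeric(time_points), rfu = rfu,
                 meta = list(compound = compound,
                             concentration = concentration)),
            class = "kinetic_trace")
}

#' Read kinetic traces from CSV
#'
#' Expects columns `time`, one or more replicate columns (any name
#' starting with `rfu`), and optional `compound` / `concentration`
#' metadata columns; one trace per compound x concentration group.
#'
#' @param path CSV file path.
#' @return list of `kinetic_trace` objects.
#' @export
read_kinetic_traces <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!"time" %in% names(tab)) stop("CSV must have a 'time' column")
  rep_cols <- grep("^rfu", names(tab), value = TRUE)
  if (!length(rep_cols)) stop("CSV must have at least one 'rfu*' replicate column")
  grp <- interaction(
    tab[["compound"]] %||% rep("sample", nrow(tab)),
    tab[["concentration"]] %||% rep(NA, nrow(tab)),
    drop = TRUE
  )
  lapply(split(tab, grp), function(df) {
    df <- df[order(df$time), , drop = FALSE]
    kinetic_trace(df$time, as.matrix(df[, rep_cols, drop = FALSE]),
                  compound = df[["compound"]][1] %||% NA_character_,
                  concentration = df[["concentration"]][1] %||% NA_real_)
  })
}

#' Preprocess a kinetic trace
#'
#' Averages replicate readings at each time point and subtracts the
#' initial reading so the trace starts at zero.
#'
#' @param raw a `kinetic_trace`.
#' @return a `kinetic_trace` with a single averaged, zero-shifted column.
#' @export
preprocess_trace <- function(raw) {
  stopifnot(inherits(raw, "kinetic_trace"))
  if (anyNA(raw$rfu)) stop("missing RFU readings in trace")
  avg <- rowMeans(raw$rfu)
  shifted <- avg - avg[1]
  kinetic_trace(raw$time, matrix(shifted, ncol = 1),
                compound = raw$meta$compound,
                concentration = raw$meta$concentration)
}

#' Initial-phase slope of a kinetic trace
#'
#' Ordinary least-squares slope (with intercept) over the first
#' `n_points` time points — the linear phase used to quantify enzyme
#' activity.
#'
#' @param trace a `kinetic_trace` (typically preprocessed).
#' @param n_points number of leading points to fit (default 10).
#' @return slope in RFU per minute.
#' @export
fit_slope <- function(trace, n_points = 10) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (n_points < 2) stop("need at least 2 points to fit a slope")
  if (n_points > length(trace$time)) {
    stop("n_points exceeds trace length (", length(trace$time), ")")
  }
  idx <- seq_len(n_points)
  y <- rowMeans(trace$rfu)[idx]
  t <- trace$time[idx]
  unname(stats::coef(stats::lm(y ~ t))[2])
}

#' Percent relative inhibition
#'
#' `100 * (slope_control - slope_sample) / slope_control`. Negative values
#' (sample faster than the enzyme control) are reported as-is rather than
#' clamped, preserving evidence of activation or assay artifacts.
#'
#' @param slope_sample initial-phase slope of the sample.
#' @param slope_enzyme_control initial-phase slope of the uninhibited
#'   enzyme control; must be positive.
#' @return percent inhibition.
#' @export
relative_inhibition <- function(slope_sample, slope_enzyme_control) {
  if (!is.finite(slope_enzyme_control) || slope_enzyme_control <= 0) {
    stop("enzyme control slope must be positive (assay failure otherwise)")
  }
  100 * (slope_enzyme_control - slope_sample) / slope_enzyme_control
}
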