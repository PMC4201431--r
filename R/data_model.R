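#' Construct a validated repeated-count dataset
#'
#' Bundles visit-level counts of unique individuals with site-level and
#' visit-level covariates into the container used by all fitting functions.
#' The layout follows the robust design: `n_sites` sites are each surveyed
#' on `n_visits` secondary visits within each of `n_seasons` primary
#' seasons, and the population is assumed closed within a season but open
#' between seasons.
#'
#' @param counts data.frame with columns `site`, `season`, `visit`,
#'   `count`, plus any visit-level covariates (e.g. precipitation,
#'   Julian day, trap height class, year). One row per site x season x
#'   visit; every combination must be present exactly once.
#' @param sites data.frame with column `site` plus site-level covariates
#'   (e.g. snag basal area in m2/ha, conifer basal area in m2/ha, a 0/1
#'   nest-box treatment indicator). One row per site.
#' @param centering optional named numeric vector of centering constants
#'   already applied to covariates (used by [center_covariates()]).
#'
#' @return An object of class `count_dataset`: a list with elements
#'   `counts`, `sites`, `centering`, `n_sites`, `n_seasons`, `n_visits`.
#' @seealso [read_count_data()], [center_covariates()],
#'   [build_design_matrix()]
#' @export
count_dataset <- function(counts, sites, centering = NULL) {
  counts <- as.data.frame(counts)
  sites <- as.data.frame(sites)
  req <- c("site", "season", "visit", "count")
  miss <- setdiff(req, names(counts))
  if (length(miss) > 0L) {
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"site" %in% names(sites)) stop("site table is missing column 'site'")
  if (anyDuplicated(sites$site)) stop("duplicated site in site table")

  cnt <- counts$count
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be finite non-negative integers")
  }
  counts$count <- as.integer(cnt)
  counts$season <- as.integer(counts$season)
  counts$visit <- as.integer(counts$visit)

  seasons <- sort(unique(counts$season))
  visits <- sort(unique(counts$visit))
  site_ids <- sites$site
  if (!setequal(unique(counts$site), site_ids)) {
    stop("site identifiers in count and site tables do not match")
  }
  expected <- length(site_ids) * length(seasons) * length(visits)
  key <- interaction(counts$site, counts$season, counts$visit, drop = FALSE)
  if (nrow(counts) != expected || anyDuplicated(key)) {
    stop("every site x season x visit combination must appear exactly once")
  }

  cov_cols <- setdiff(names(counts), req)
  for (cc in c(cov_cols, setdiff(names(sites), "site"))) {
    tab <- if (cc %in% cov_cols) counts else sites
    if (!is.numeric(tab[[cc]]) || any(!is.finite(tab[[cc]]))) {
      stop("covariate '", cc, "' must be finite numeric")
    }
  }
  if ("boxes" %in% names(sites) && !all(sites$boxes %in% c(0, 1))) {
    stop("'boxes' must be coded 0/1")
  }

  # canonical ordering: site-major, then season, then visit
  ord <- order(match(counts$site, site_ids), counts$season, counts$visit)
  counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- NULL

  structure(
    list(
      counts = counts, sites = sites,
      centering = centering,
      n_sites = length(site_ids),
      n_seasons = length(seasons),
      n_visits = length(visits)
    ),
    class = "count_dataset"
  )
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(
    "Repeated-count dataset:", x$n_sites, "sites x", x$n_seasons,
    "seasons x", x$n_visits, "visits\n"
  )
  cat(
    "  site covariates:",
    paste(setdiff(names(x$sites), "site"), collapse = ", "), "\n"
  )
  cat(
    "  visit covariates:",
    paste(setdiff(names(x$counts), c("site", "season", "visit", "count")),
      collapse = ", "
    ), "\n"
  )
  if (!is.null(x$centering)) {
    cat(
      "  centered:", paste(names(x$centering), collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Read a repeated-count dataset from CSV files
#'
#' Expects the long layout: one row per site x season x visit in the count
#' file, one row per site in the site file. Comma-separated, UTF-8, "."
#' decimal separator.
#'
#' @param count_file path to CSV with columns
#'   `site,season,visit,count` plus visit covariates.
#' @param site_file path to CSV with columns `site` plus site covariates.
#' @return A [count_dataset()].
#' @export
read_count_data <- function(count_file, site_file) {
  counts <- utils::read.csv(count_file, stringsAsFactors = FALSE)
  sites <- utils::read.csv(site_file, stringsAsFactors = FALSE)
  count_dataset(counts, sites)
}

#' Write a repeated-count dataset to CSV files
#'
#' Inverse of [read_count_data()]; the round trip is lossless.
#'
#' @param dataset a [count_dataset()].
#' @param count_file,site_file output paths.
#' @return Invisibly, the dataset.
#' @export
write_count_data <- function(dataset, count_file, site_file) {
  stopifnot(inherits(dataset, "count_dataset"))
  utils::write.csv(dataset$counts, count_file, row.names = FALSE)
  utils::write.csv(dataset$sites, site_file, row.names = FALSE)
  invisible(dataset)
}

#' Construct a set of individual capture histories
#'
#' Container for the capture-mark-recapture comparison estimators.
#' Occasion times are in years and strictly increasing; unequal intervals
#' are honoured by the Cormack-Jolly-Seber likelihood, which scales
#' survival as phi^interval.
#'
#' @param histories 0/1 matrix, one row per individual, one column per
#'   trapping occasion. Every individual must be detected at least once.
#' @param occasion_times numeric vector of occasion times (years),
#'   strictly increasing, length equal to `ncol(histories)`.
#' @param site optional site identifier per individual (carries
#'   site covariates into capture models).
#' @param individual optional individual identifiers.
#' @param site_covariates optional data.frame of per-individual numeric
#'   covariates (typically the covariates of the individual's site).
#' @return An object of class `capture_history_set`.
#' @export
capture_history_set <- function(histories, occasion_times,
                                site = NULL, individual = NULL,
                                site_covariates = NULL) {
  histories <- as.matrix(histories)
  if (!all(histories %in% c(0L, 1L))) stop("histories must be 0/1")
  storage.mode(histories) <- "integer"
  if (any(rowSums(histories) == 0L)) {
    stop("every individual must be detected on at least one occasion")
  }
  if (length(occasion_times) != ncol(histories)) {
    stop("occasion_times length must equal the number of occasions")
  }
  if (any(diff(occasion_times) <= 0)) {
    stop("occasion_times must be strictly increasing")
  }
  n <- nrow(histories)
  if (is.null(individual)) individual <- seq_len(n)
  if (!is.null(site) && length(site) != n) {
    stop("site must have one entry per individual")
  }
  structure(
    list(
      histories = histories,
      occasion_times = as.numeric(occasion_times),
      site = site, individual = individual,
      site_covariates = site_covariates
    ),
    class = "capture_history_set"
  )
}

#' @export
print.capture_history_set <- function(x, ...) {
  cat(
    "Capture histories:", nrow(x$histories), "individuals x",
    ncol(x$histories), "occasions at times",
    paste(x$occasion_times, collapse = ", "), "\n"
  )
  invisible(x)
}

#' Read capture histories from CSV
#'
#' Columns: `individual`, `site`, `history` (string of 0/1 over
#' occasions), `occasion_times` (semicolon-separated reals, identical for
#' every row).
#'
#' @param path CSV file path.
#' @param site_table optional site data.frame to attach covariates.
#' @return A [capture_history_set()].
#' @export
read_capture_histories <- function(path, site_table = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(history = "character"))
  req <- c("individual", "site", "history", "occasion_times")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0L) {
    stop("history file is missing column(s): ", paste(miss, collapse = ", "))
  }
  occ <- as.numeric(strsplit(d$occasion_times[1L], ";")[[1L]])
  hist <- t(vapply(
    strsplit(d$history, ""),
    function(h) as.integer(h),
    integer(length(occ))
  ))
  covs <- NULL
  if (!is.null(site_table)) {
    covs <- site_table[match(d$site, site_table$site),
                       setdiff(names(site_table), "site"),
                       drop = FALSE]
    rownames(covs) <- NULL
  }
  capture_history_set(hist, occ,
    site = d$site, individual = d$individual,
    site_covariates = covs
  )
}

#' Write capture histories to CSV
#' @param histories a [capture_history_set()].
#' @param path output CSV path.
#' @return Invisibly, the input.
#' @export
write_capture_histories <- function(histories, path) {
  stopifnot(inherits(histories, "capture_history_set"))
  d <- data.frame(
    individual = histories$individual,
    site = if (is.null(histories$site)) NA else histories$site,
    history = apply(histories$histories, 1L, paste0, collapse = ""),
    occasion_times = paste(histories$occasion_times, collapse = ";")
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(histories)
}

# truncate (not round) x to `digits` decimals; the convention used for
# capture rates per 100 trap-nights
trunc_dec <- function(x, digits) trunc(x * 10^digits) / 10^digits

#' Descriptive capture summary
#'
#' Tabulates trapping effort and capture rates the way field studies
#' report them: mean unique individuals per site rounded to one decimal,
#' captures per 100 trap-nights truncated to two decimals.
#'
#' @param unique_per_year named integer vector: unique individuals
#'   captured in each year.
#' @param n_sites number of trapping sites.
#' @param trap_nights_per_site trap-nights of effort per site per year
#'   (default 48: 8 stations x 3 nights x 2 visits).
#' @param total_captures optional total capture events (with recaptures).
#' @return A list of class `capture_summary` with per-year means and
#'   rates and the total trap-nights.
#' @export
summarize_captures <- function(unique_per_year, n_sites,
                               trap_nights_per_site = 48,
                               total_captures = NULL) {
  if (n_sites <= 0) stop("n_sites must be positive")
  trap_nights <- n_sites * trap_nights_per_site
  if (trap_nights <= 0) stop("trap-nights must be positive")
  mean_per_site <- round(unique_per_year / n_sites, 1L)
  rate <- trunc_dec(100 * unique_per_year / trap_nights, 2L)
  structure(
    list(
      unique_individuals_per_year = unique_per_year,
      total_captures = total_captures,
      n_sites = n_sites,
      trap_nights = trap_nights,
      mean_unique_per_site = mean_per_site,
      captures_per_100_trapnights = rate
    ),
    class = "capture_summary"
  )
}

#' @export
print.capture_summary <- function(x, ...) {
  cat("Capture summary over", x$trap_nights, "trap-nights per year\n")
  for (i in seq_along(x$unique_individuals_per_year)) {
    nm <- names(x$unique_individuals_per_year)[i]
    cat(
      if (is.null(nm) || nm == "") paste0("year ", i) else nm, ":",
      x$unique_individuals_per_year[i], "unique individuals,",
      "mean", x$mean_unique_per_site[i], "per site,",
      x$captures_per_100_trapnights[i], "per 100 trap-nights\n"
    )
  }
  invisible(x)
}

#' Centre covariates and store the centering constants
#'
#' Subtracts the mean of each named covariate across its design rows
#' (site rows for site covariates, count rows for visit covariates).
#' Constants are stored on the dataset so predictions can be made on the
#' raw covariate scale.
#'
#' @param dataset a [count_dataset()].
#' @param names character vector of covariate names to centre; default
#'   all numeric covariates except 0/1 indicators.
#' @return The dataset with centred covariates and a `centering` vector.
#' @export
center_covariates <- function(dataset, names = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  site_covs <- setdiff(base::names(dataset$sites), "site")
  visit_covs <- setdiff(
    base::names(dataset$counts),
    c("site", "season", "visit", "count")
  )
  if (is.null(names)) {
    is01 <- function(v) all(v %in% c(0, 1))
    names <- c(
      site_covs[!vapply(dataset$sites[site_covs], is01, logical(1))],
      visit_covs[!vapply(dataset$counts[visit_covs], is01, logical(1))]
    )
  }
  centering <- dataset$centering
  if (is.null(centering)) centering <- numeric(0)
  for (nm in names) {
    if (nm %in% site_covs) {
      m <- mean(dataset$sites[[nm]])
      dataset$sites[[nm]] <- dataset$sites[[nm]] - m
    } else if (nm %in% visit_covs) {
      m <- mean(dataset$counts[[nm]])
      dataset$counts[[nm]] <- dataset$counts[[nm]] - m
    } else {
      stop("unknown covariate: ", nm)
    }
    centering[nm] <- unname(m) + if (nm %in% base::names(centering)) {
      centering[[nm]]
    } else {
      0
    }
  }
  dataset$centering <- centering
  dataset
}

#' Flag collinear covariate pairs
#'
#' Computes pairwise Pearson correlations among site covariates and
#' returns the pairs exceeding the threshold in absolute value; such
#' pairs should not enter the same model formula.
#'
#' @param dataset a [count_dataset()].
#' @param threshold absolute correlation above which a pair is flagged
#'   (default 0.7).
#' @return data.frame with columns `var1`, `var2`, `r` for flagged pairs
#'   (zero rows if none). Constant covariates are skipped with a warning.
#' @export
screen_collinearity <- function(dataset, threshold = 0.7) {
  stopifnot(inherits(dataset, "count_dataset"))
  covs <- dataset$sites[, setdiff(names(dataset$sites), "site"),
                        drop = FALSE]
  if (nrow(covs) < 2L) stop("need at least two sites")
  keep <- vapply(covs, function(v) stats::sd(v) > 0, logical(1))
  if (any(!keep)) {
    warning(
      "constant covariate(s) skipped: ",
      paste(names(covs)[!keep], collapse = ", ")
    )
  }
  covs <- covs[, keep, drop = FALSE]
  out <- data.frame(
    var1 = character(0), var2 = character(0),
    r = numeric(0), stringsAsFactors = FALSE
  )
  nms <- names(covs)
  if (length(nms) >= 2L) {
    cm <- stats::cor(covs)
    for (i in seq_len(length(nms) - 1L)) {
      for (j in seq(i + 1L, length(nms))) {
        if (abs(cm[i, j]) > threshold) {
          out <- rbind(out, data.frame(
            var1 = nms[i], var2 = nms[j], r = cm[i, j],
            stringsAsFactors = FALSE
          ))
        }
      }
    }
  }
  out
}

#' Build a design matrix for one model parameter
#'
#' Expands an R model formula (e.g. `~ boxes * snag_ba`) against the
#' covariates at the resolution the parameter requires: site rows for
#' initial abundance and recruitment, site x season x visit rows for
#' detection. An intercept is always included; `A * B` expands to
#' `A + B + A:B` in the usual way.
#'
#' @param dataset a [count_dataset()].
#' @param formula one-sided R formula over covariate names (use `~ 1`
#'   for intercept-only).
#' @param level `"site"` or `"observation"`.
#' @return Numeric design matrix with column names.
#' @export
build_design_matrix <- function(dataset, formula,
                                level = c("site", "observation")) {
  stopifnot(inherits(dataset, "count_dataset"))
  level <- match.arg(level)
  formula <- stats::as.formula(formula)
  frame <- if (level == "site") {
    dataset$sites
  } else {
    # observation rows carry both visit- and site-level covariates
    merge_covs <- dataset$sites[
      match(dataset$counts$site, dataset$sites$site),
      setdiff(names(dataset$sites), "site"),
      drop = FALSE
    ]
    cbind(dataset$counts, merge_covs)
  }
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(frame))
  if (length(miss) > 0L) {
    stop("unknown covariate(s) in formula: ", paste(miss, collapse = ", "))
  }
  stats::model.matrix(formula, data = frame)
}
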