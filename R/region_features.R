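# Regional moment features: each cortical region's thickness distribution is
# summarized by (mean, SD, skewness, kurtosis) and the N regions of a scan
# are stacked into an N x 4 feature matrix X.

#' Parcellation atlas descriptor
#'
#' @param name One of `"desikan-killiany"` (N = 68), `"destrieux"` (N = 148),
#'   `"glasser"` (N = 360), or `"custom"` with `n_regions` supplied.
#' @param n_regions Region count; required for `"custom"`, otherwise derived
#'   from the atlas name (and checked if given).
#' @param region_names Optional character vector of region names.
#' @return Object of class `parcellation` with fields `name`, `n_regions`,
#'   `region_ids` (the fixed node ordering `1:N`) and `region_names`.
#' @export
parcellation <- function(name = c("desikan-killiany", "destrieux", "glasser", "custom"),
                         n_regions = NULL, region_names = NULL) {
  name <- match.arg(name)
  known <- c("desikan-killiany" = 68L, "destrieux" = 148L, "glasser" = 360L)
  if (name == "custom") {
    if (is.null(n_regions)) stop("custom parcellation needs n_regions")
  } else {
    if (!is.null(n_regions) && n_regions != known[[name]]) {
      stop(sprintf("atlas '%s' has %d regions, not %d", name, known[[name]], n_regions))
    }
    n_regions <- known[[name]]
  }
  n_regions <- as.integer(n_regions)
  if (!is.null(region_names) && length(region_names) != n_regions) {
    stop("region_names must have length n_regions")
  }
  structure(list(name = name, n_regions = n_regions,
                 region_ids = seq_len(n_regions), region_names = region_names),
            class = "parcellation")
}

#' Summarize one region's thickness values by its first four moments
#'
#' Population (divide-by-n) moments: mean, SD, moment skewness
#' \eqn{m_3/m_2^{3/2}} and non-excess moment kurtosis \eqn{m_4/m_2^2}. A
#' zero-variance region gets skewness and kurtosis 0 by convention so the
#' feature matrix stays finite. `sample_moments = TRUE` switches to the
#' unbiased variance (n-1) and the adjusted Fisher-Pearson skewness /
#' sample kurtosis.
#'
#' @param values Numeric vector of thickness values (mm), non-empty, finite.
#' @param sample_moments Use sample-adjusted estimators instead of population
#'   moments (default `FALSE`).
#' @param region Optional region id used in error messages.
#' @return Named numeric vector `c(mu, sigma, gamma, k)`.
#' @examples
#' summarize_region(c(1, 2, 3, 4, 5))  # (3, sqrt(2), 0, 1.7)
#' @export
summarize_region <- function(values, sample_moments = FALSE, region = NULL) {
  tag <- if (is.null(region)) "" else paste0(" (region ", region, ")")
  if (length(values) == 0) stop("empty region", tag)
  if (!all(is.finite(values))) stop("non-finite thickness value", tag)
  n <- length(values)
  mu <- mean(values)
  d <- values - mu
  m2 <- mean(d^2)
  if (m2 == 0) return(c(mu = mu, sigma = 0, gamma = 0, k = 0))
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  if (!sample_moments) {
    c(mu = mu, sigma = sqrt(m2), gamma = m3 / m2^1.5, k = m4 / m2^2)
  } else {
    s2 <- m2 * n / (n - 1)
    g1 <- m3 / m2^1.5
    G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
    G2 <- ((n + 1) * (m4 / m2^2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3)) + 3
    c(mu = mu, sigma = sqrt(s2), gamma = G1, k = G2)
  }
}

stat_names <- c("mu", "sigma", "gamma", "k")

# Fast grouped moment computation on a long thickness table.
# Returns data.table(scan_id, region_id, n, mu, sigma, gamma, k).
moment_table <- function(thickness) {
  region_id <- scan_id <- thickness_mm <- NULL # NSE notes
  thickness[, {
    n <- .N
    mu <- mean(thickness_mm)
    d <- thickness_mm - mu
    m2 <- mean(d^2)
    if (m2 == 0) {
      list(n = n, mu = mu, sigma = 0, gamma = 0, k = 0)
    } else {
      list(n = n, mu = mu, sigma = sqrt(m2),
           gamma = mean(d^3) / m2^1.5, k = mean(d^4) / m2^2)
    }
  }, by = c("scan_id", "region_id")]
}

#' Build the N x 4 feature matrix of one scan
#'
#' Rows follow the parcellation's fixed region ordering; columns are
#' (mu, sigma, gamma, k). Every region must be present with at least
#' `min_vertices` values — small regions make the third and fourth moments
#' meaningless, so such scans are rejected rather than imputed.
#'
#' @param scan Either a long-format `data.frame`/`data.table` with columns
#'   `region_id` and `thickness_mm` (a single scan), or a `scan_cohort`
#'   together with `scan_id=`.
#' @param parc A [parcellation()].
#' @param scan_id Scan to extract when `scan` is a `scan_cohort`.
#' @param min_vertices Minimum vertex count per region (default 10).
#' @param sample_moments Passed to [summarize_region()].
#' @return Numeric matrix N x 4 of class `feature_matrix` with attributes
#'   `scan_id` and `parcellation`.
#' @export
build_feature_matrix <- function(scan, parc, scan_id = NULL,
                                 min_vertices = 10L, sample_moments = FALSE) {
  stopifnot(inherits(parc, "parcellation"))
  if (inherits(scan, "scan_cohort")) {
    if (is.null(scan_id)) stop("scan_id required when passing a scan_cohort")
    sid <- scan_id
    tab <- scan$thickness[scan$thickness$scan_id == sid, ]
  } else {
    tab <- data.table::as.data.table(scan)
    sid <- scan_id
  }
  if (!all(c("region_id", "thickness_mm") %in% names(tab))) {
    stop("scan table needs columns region_id and thickness_mm")
  }
  N <- parc$n_regions
  if (any(tab$region_id < 1 | tab$region_id > N)) {
    stop("region_id outside [1, ", N, "]")
  }
  present <- sort(unique(tab$region_id))
  missing <- setdiff(parc$region_ids, present)
  if (length(missing)) {
    stop("scan is missing regions: ", paste(missing, collapse = ", "))
  }
  counts <- table(tab$region_id)
  small <- as.integer(names(counts))[counts < min_vertices]
  if (length(small)) {
    stop("regions below min_vertices (", min_vertices, "): ",
         paste(small, collapse = ", "), "; scan rejected")
  }
  X <- matrix(0.0, nrow = N, ncol = 4,
              dimnames = list(parc$region_ids, stat_names))
  split_vals <- split(tab$thickness_mm, tab$region_id)
  for (r in parc$region_ids) {
    X[r, ] <- summarize_region(split_vals[[as.character(r)]],
                               sample_moments = sample_moments, region = r)
  }
  structure(X, class = c("feature_matrix", "matrix", "array"),
            scan_id = sid, parcellation = parc$name)
}

#' Feature matrices for every scan of a cohort
#'
#' Vectorized over scans (grouped moments on the long table); equivalent to
#' calling [build_feature_matrix()] per scan.
#'
#' @param cohort A `scan_cohort`.
#' @param parc A [parcellation()] whose `n_regions` matches the cohort.
#' @param min_vertices Minimum vertex count per region.
#' @return Named list of `feature_matrix` objects, one per scan, in
#'   metadata order.
#' @export
featurize_cohort <- function(cohort, parc, min_vertices = 10L) {
  stopifnot(inherits(cohort, "scan_cohort"), inherits(parc, "parcellation"))
  N <- parc$n_regions
  mt <- moment_table(cohort$thickness)
  if (any(mt$n < min_vertices)) {
    bad <- unique(mt$scan_id[mt$n < min_vertices])
    stop("regions below min_vertices in scans: ", paste(bad, collapse = ", "))
  }
  counts <- mt[, .N, by = "scan_id"]
  if (any(counts$N != N)) {
    stop("scans with missing regions: ",
         paste(counts$scan_id[counts$N != N], collapse = ", "))
  }
  data.table::setorderv(mt, c("scan_id", "region_id"))
  out <- lapply(split(mt, by = "scan_id", sorted = FALSE), function(g) {
    X <- as.matrix(g[, c("mu", "sigma", "gamma", "k"), with = FALSE])
    dimnames(X) <- list(g$region_id, stat_names)
    structure(X, class = c("feature_matrix", "matrix", "array"),
              scan_id = g$scan_id[1], parcellation = parc$name)
  })
  out[cohort$metadata$scan_id]
}

#' Whole-brain mean cortical thickness of a scan
#'
#' Vertex-weighted mean over all cortical vertices. If only region-level
#' features are available, falls back to a vertex-count-weighted mean of the
#' region means when counts are known, otherwise to the unweighted mean of
#' region means (with a warning).
#'
#' @param scan Long-format table with `thickness_mm` (vertex level), or a
#'   `feature_matrix` (region level; supply `vertex_counts` if known).
#' @param vertex_counts Optional vector of per-region vertex counts for the
#'   region-level fallback.
#' @return Mean thickness (mm).
#' @export
whole_brain_mean_thickness <- function(scan, vertex_counts = NULL) {
  if (inherits(scan, "feature_matrix")) {
    mu <- scan[, "mu"]
    if (!is.null(vertex_counts)) {
      if (length(vertex_counts) != length(mu)) {
        stop("vertex_counts length must match region count")
      }
      return(sum(mu * vertex_counts) / sum(vertex_counts))
    }
    warning("no vertex data: using unweighted mean of region means")
    return(mean(mu))
  }
  tab <- data.table::as.data.table(scan)
  if (!"thickness_mm" %in% names(tab)) stop("no vertex data available")
  mean(tab$thickness_mm)
}

#' Read region features from a pre-summarized TSV
#'
#' Expects columns `region_id, mu, sigma, gamma, k`.
#'
#' @param path TSV file path.
#' @param parc A [parcellation()]; all regions must be present.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, parc) {
  tab <- data.table::fread(path, sep = "\t")
  need <- c("region_id", stat_names)
  if (!all(need %in% names(tab))) {
    stop("feature table needs columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(parc$region_ids, tab$region_id)
  if (length(missing)) {
    stop("feature table missing regions: ", paste(missing, collapse = ", "))
  }
  data.table::setorderv(tab, "region_id")
  X <- as.matrix(tab[, stat_names, with = FALSE])
  dimnames(X) <- list(tab$region_id, stat_names)
  structure(X, class = c("feature_matrix", "matrix", "array"),
            scan_id = NULL, parcellation = parc$name)
}

#' Read a FreeSurfer cortical-parcellation stats table
#'
#' Parses the plain-text `aparc.stats`-style format: comment lines starting
#' with `#`, a `# ColHeaders ...` line naming the columns, then one row per
#' region. Returns the region table with `ThickAvg`/`ThickStd` renamed to
#' `mu`/`sigma`. These tables carry only the first two moments, so they
#' cannot feed the 4-moment feature matrix directly: [as_feature_matrix()]
#' rejects them unless skewness and kurtosis columns are supplied alongside.
#'
#' @param path Path to the stats text file.
#' @return `data.frame` with at least `region_name`, `n_vertices`, `mu`,
#'   `sigma`.
#' @export
read_aparc_stats <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ColHeaders", lines, value = TRUE)
  if (length(hdr) != 1) stop("no '# ColHeaders' line found in ", path)
  cols <- strsplit(sub("^# ColHeaders\\s+", "", hdr), "\\s+")[[1]]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path)
  tab <- utils::read.table(text = body, col.names = cols,
                           stringsAsFactors = FALSE)
  need <- c("StructName", "NumVert", "ThickAvg", "ThickStd")
  if (!all(need %in% cols)) {
    stop("stats table lacks required columns: ",
         paste(setdiff(need, cols), collapse = ", "))
  }
  out <- data.frame(region_name = tab$StructName, n_vertices = tab$NumVert,
                    mu = tab$ThickAvg, sigma = tab$ThickStd)
  out
}

#' Assemble a feature matrix from pre-summarized region statistics
#'
#' @param tab `data.frame` with `mu` and `sigma` (e.g. from
#'   [read_aparc_stats()]) in parcellation order.
#' @param parc A [parcellation()] with matching region count.
#' @param gamma,k Per-region skewness and kurtosis. The pipeline's node
#'   features are the first four moments; tables carrying only mean and SD
#'   are rejected rather than zero-filled, because missing higher moments
#'   would silently distort the distances.
#' @return A `feature_matrix`.
#' @export
as_feature_matrix <- function(tab, parc, gamma = NULL, k = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  if (nrow(tab) != parc$n_regions) {
    stop("table has ", nrow(tab), " regions but parcellation has ",
         parc$n_regions)
  }
  if (is.null(gamma) || is.null(k)) {
    stop("mean/SD-only tables cannot form the 4-moment feature matrix; ",
         "supply per-region gamma and k")
  }
  X <- cbind(mu = tab$mu, sigma = tab$sigma, gamma = gamma, k = k)
  rownames(X) <- parc$region_ids
  structure(X, class = c("feature_matrix", "matrix", "array"),
            scan_id = NULL, parcellation = parc$name)
}

#' Write a feature matrix as TSV
#' @param X A `feature_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  tab <- data.table::data.table(region_id = as.integer(rownames(X)),
                                mu = X[, "mu"], sigma = X[, "sigma"],
                                gamma = X[, "gamma"], k = X[, "k"])
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
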