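# Age/sex normalization of region features, fitted on healthy-control scans
# only. Two schemes:
#  - proportional: whole-brain mean thickness Cth is regressed on age per sex
#    (Cth = a*age + b); a scan is rescaled to reference age 20 by
#    alpha = Cth20/Cth with Cth20 = a*20 + Cth - a*age, applied to the mu and
#    sigma columns only.
#  - residual: per sex, per region, per statistic, an OLS fit statistic ~ age;
#    the adjusted feature is the residual, oriented predicted - observed.

REFERENCE_AGE <- 20

check_healthy_fit_input <- function(meta, min_per_sex = 10L) {
  sexes <- unique(meta$sex)
  if (!all(c("F", "M") %in% sexes)) {
    stop("both sexes are required to fit the normalization model; found only: ",
         paste(sexes, collapse = ", "))
  }
  for (sx in c("F", "M")) {
    sub <- meta[meta$sex == sx, ]
    if (nrow(sub) < min_per_sex) {
      stop("need at least ", min_per_sex, " healthy scans for sex ", sx)
    }
    if (stats::var(sub$age_years) == 0) {
      stop("age is constant for sex ", sx, "; cannot regress on age")
    }
  }
  invisible(TRUE)
}

#' Fit the proportional age/sex normalization model
#'
#' Per-sex ordinary least squares of whole-brain mean cortical thickness on
#' age, using healthy-control scans only.
#'
#' @param healthy A `scan_cohort` of healthy scans, or a `data.frame` with
#'   columns `age_years`, `sex` and `cth` (whole-brain mean thickness, mm).
#' @param min_per_sex Minimum number of scans required per sex (default 10).
#' @return Object of class `proportional_model`: list with per-sex
#'   `coefficients` (`a` slope mm/year, `b` intercept mm), `n_fit` and
#'   `reference_age`.
#' @export
fit_proportional <- function(healthy, min_per_sex = 10L) {
  tab <- healthy_cth_table(healthy)
  check_healthy_fit_input(tab, min_per_sex)
  coefs <- lapply(c(F = "F", M = "M"), function(sx) {
    sub <- tab[tab$sex == sx, ]
    fit <- stats::lm(cth ~ age_years, data = sub)
    c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
  })
  structure(list(coefficients = coefs,
                 n_fit = c(F = sum(tab$sex == "F"), M = sum(tab$sex == "M")),
                 reference_age = REFERENCE_AGE),
            class = "proportional_model")
}

healthy_cth_table <- function(healthy) {
  if (inherits(healthy, "scan_cohort")) {
    scan_id <- thickness_mm <- NULL
    cth <- healthy$thickness[, list(cth = mean(thickness_mm)), by = "scan_id"]
    tab <- merge(healthy$metadata, cth, by = "scan_id", sort = FALSE)
    as.data.frame(tab[tab$label == "HC", ])
  } else {
    tab <- as.data.frame(healthy)
    if (!all(c("age_years", "sex", "cth") %in% names(tab))) {
      stop("healthy table needs columns age_years, sex, cth")
    }
    tab
  }
}

#' Apply the proportional correction to a feature matrix
#'
#' Computes `Cth20 = a*20 + Cth - a*age` with the slope of the scan's sex,
#' `alpha = Cth20/Cth`, and rescales the mean and SD columns:
#' `x' = (alpha*mu, alpha*sigma, gamma, k)`. Skewness and kurtosis are scale
#' invariant and pass through unchanged. At the reference age (20 years)
#' `alpha = 1` for any scan.
#'
#' @param X A `feature_matrix`.
#' @param age,sex Scan age (years) and sex (`"F"`/`"M"`).
#' @param cth Whole-brain mean thickness of the scan (mm); see
#'   [whole_brain_mean_thickness()].
#' @param model A fitted [fit_proportional()] model.
#' @return Adjusted `feature_matrix` with attributes `norm_mode =
#'   "proportional"` and `alpha`.
#' @export
apply_proportional <- function(X, age, sex, cth, model) {
  stopifnot(inherits(model, "proportional_model"))
  if (is.na(age) || is.null(age)) stop("scan age is missing")
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'")
  if (cth <= 0) stop("whole-brain mean thickness must be positive")
  a <- model$coefficients[[sex]][["a"]]
  cth20 <- a * model$reference_age + cth - a * age
  alpha <- cth20 / cth
  out <- X
  out[, "mu"] <- alpha * X[, "mu"]
  out[, "sigma"] <- alpha * X[, "sigma"]
  attr(out, "norm_mode") <- "proportional"
  attr(out, "alpha") <- alpha
  out
}

#' Fit the residual age/sex normalization model
#'
#' For each sex, region and statistic (mu, sigma, gamma, k), fits the OLS
#' regression statistic ~ age on healthy scans. Stores 2 x N x 4 slope and
#' intercept pairs.
#'
#' @param features Named list of `feature_matrix` objects for the healthy
#'   scans (e.g. from [featurize_cohort()]).
#' @param meta `data.frame` with `scan_id`, `age_years`, `sex` matching
#'   `features`.
#' @param min_per_sex Minimum scans per sex (default 10).
#' @return Object of class `residual_model`: list with `slope` and
#'   `intercept`, each a named list (`F`, `M`) of N x 4 matrices, plus
#'   `n_fit`.
#' @export
fit_residual <- function(features, meta, min_per_sex = 10L) {
  meta <- as.data.frame(meta)
  meta <- meta[match(names(features), meta$scan_id), ]
  if (any(is.na(meta$scan_id))) stop("metadata missing for some feature matrices")
  check_healthy_fit_input(meta, min_per_sex)
  N <- nrow(features[[1]])
  # stack: scans x (N*4)
  flat <- t(vapply(features, function(X) as.vector(X), numeric(N * 4)))
  fit_sex <- function(sx) {
    sel <- meta$sex == sx
    age <- meta$age_years[sel]
    Y <- flat[sel, , drop = FALSE]
    age_c <- age - mean(age)
    slope <- colSums(age_c * Y) / sum(age_c^2)
    intercept <- colMeans(Y) - slope * mean(age)
    list(slope = matrix(slope, N, 4, dimnames = list(rownames(features[[1]]), stat_names)),
         intercept = matrix(intercept, N, 4, dimnames = list(rownames(features[[1]]), stat_names)))
  }
  fits <- lapply(c(F = "F", M = "M"), fit_sex)
  if (!all(vapply(fits, function(f) all(is.finite(f$slope)) && all(is.finite(f$intercept)), TRUE))) {
    stop("non-finite residual-model coefficients")
  }
  structure(list(slope = lapply(fits, `[[`, "slope"),
                 intercept = lapply(fits, `[[`, "intercept"),
                 n_fit = c(F = sum(meta$sex == "F"), M = sum(meta$sex == "M"))),
            class = "residual_model")
}

#' Apply the residual correction to a feature matrix
#'
#' Replaces each entry by the residual from the healthy regression of that
#' sex, region and statistic. The residual is oriented predicted minus
#' observed, `r = a*age + b - x` (set `flip_sign = TRUE` for the conventional
#' observed-minus-predicted orientation).
#'
#' @param X A `feature_matrix`.
#' @param age,sex Scan age (years) and sex.
#' @param model A fitted [fit_residual()] model.
#' @param flip_sign Use observed - predicted instead (default `FALSE`).
#' @return Adjusted `feature_matrix` with attribute `norm_mode = "residual"`.
#' @export
apply_residual <- function(X, age, sex, model, flip_sign = FALSE) {
  stopifnot(inherits(model, "residual_model"))
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'")
  S <- model$slope[[sex]]
  B <- model$intercept[[sex]]
  if (!all(dim(S) == dim(X))) {
    stop("region/statistic mismatch between feature matrix (", nrow(X),
         " regions) and model (", nrow(S), " regions)")
  }
  R <- S * age + B - unclass(X)
  if (flip_sign) R <- -R
  out <- X
  out[, ] <- R
  attr(out, "norm_mode") <- "residual"
  out
}

#' Normalize every scan of a featurized cohort
#'
#' Convenience wrapper dispatching on the normalization mode. Models must be
#' fitted beforehand on healthy scans; patient scans are only ever corrected.
#'
#' @param features Named list of `feature_matrix` (one per scan).
#' @param meta Metadata `data.frame` with `scan_id`, `age_years`, `sex`.
#' @param mode `"none"`, `"proportional"` or `"residual"`.
#' @param model The fitted model matching `mode` (ignored for `"none"`).
#' @param cth Named numeric vector of whole-brain mean thickness per scan
#'   (required for proportional mode).
#' @return Named list of adjusted feature matrices.
#' @export
normalize_features <- function(features, meta, mode = c("none", "proportional", "residual"),
                               model = NULL, cth = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(features)
  meta <- as.data.frame(meta)
  idx <- match(names(features), meta$scan_id)
  if (any(is.na(idx))) stop("metadata missing for some scans")
  out <- vector("list", length(features))
  names(out) <- names(features)
  for (i in seq_along(features)) {
    m <- meta[idx[i], ]
    out[[i]] <- switch(mode,
      proportional = {
        if (is.null(cth)) stop("proportional mode needs per-scan cth values")
        apply_proportional(features[[i]], m$age_years, m$sex,
                           cth[[m$scan_id]], model)
      },
      residual = apply_residual(features[[i]], m$age_years, m$sex, model)
    )
  }
  out
}

#' Serialize a fitted normalization model to JSON
#' @param model A `proportional_model` or `residual_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_norm_model <- function(model, path) {
  if (inherits(model, "proportional_model")) {
    obj <- list(mode = "proportional",
                coefficients = lapply(model$coefficients, as.list),
                n_fit = as.list(model$n_fit),
                reference_age = model$reference_age)
  } else if (inherits(model, "residual_model")) {
    obj <- list(mode = "residual",
                slope = lapply(model$slope, function(m) as.data.frame(m)),
                intercept = lapply(model$intercept, function(m) as.data.frame(m)),
                n_fit = as.list(model$n_fit))
  } else stop("not a normalization model")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a normalization model written by [write_norm_model()]
#' @param path JSON path.
#' @return The model object.
#' @export
read_norm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$mode == "proportional") {
    structure(list(coefficients = lapply(obj$coefficients, unlist),
                   n_fit = unlist(obj$n_fit),
                   reference_age = obj$reference_age),
              class = "proportional_model")
  } else if (obj$mode == "residual") {
    tomat <- function(df) {
      m <- as.matrix(df)
      dimnames(m) <- list(seq_len(nrow(m)), stat_names)
      m
    }
    structure(list(slope = lapply(obj$slope, tomat),
                   intercept = lapply(obj$intercept, tomat),
                   n_fit = unlist(obj$n_fit)),
              class = "residual_model")
  } else stop("unknown model mode: ", obj$mode)
}
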