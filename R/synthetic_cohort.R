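# Synthetic longitudinal cohort simulator.
#
# Emulates the statistical structure a morphological-connectivity pipeline
# assumes in a multiple-sclerosis T1w study: per-region cortical thickness
# with healthy age-related thinning (sex-specific slopes), class-specific
# regional atrophy, repeated scans per patient, and a skewed within-region
# vertex distribution so that third/fourth moments carry signal.

#' Simulation configuration for a synthetic thickness cohort
#'
#' Defines the generative model used by [simulate_cohort()] and
#' [simulate_healthy_reference()]. Thickness of a vertex v in region r of a
#' scan is
#' \deqn{t_{v} = \beta_r + a_{sex} \cdot age + s_{sex} + \delta_{class,r} +
#'   u_{patient} + e_{scan} + \epsilon_v}
#' where \eqn{\beta_r} is the region baseline (drawn once per configuration),
#' \eqn{a_{sex}} the healthy thinning slope, \eqn{\delta_{class,r}} the extra
#' thinning (mm) in the class's affected region subset, \eqn{u, e} patient and
#' scan random intercepts and \eqn{\epsilon_v} skew-normal vertex noise.
#' Values are truncated below at 0.5 mm so all draws stay physical.
#'
#' @param atlas_size Number of cortical regions N (68, 148 or 360 for the
#'   named atlases; any positive integer is accepted).
#' @param vertices_per_region Vertices simulated per region (default 200).
#' @param n_patients_per_class Named integer vector, patients per clinical
#'   form. Defaults to the study-scale cohort `c(RR = 42, PP = 21, SP = 28,
#'   HC = 21)`.
#' @param scans_per_class Named integer vector of total scan counts per class;
#'   scans are distributed as evenly as possible over the class's patients
#'   (first patients receive the remainder). Default
#'   `c(RR = 299, PP = 143, SP = 218, HC = 21)`. Alternatively give
#'   `scans_per_patient` (single integer) to override.
#' @param scans_per_patient Optional fixed number of scans for every patient;
#'   overrides `scans_per_class` when non-`NULL`.
#' @param baseline_mean_mm Either `NULL` (region baselines drawn once from
#'   `baseline_range_mm`) or a numeric vector of length `atlas_size`.
#' @param baseline_range_mm Range for baseline draws, default `c(2, 3)` mm.
#' @param healthy_slope_mm_per_year Named vector `c(F = , M = )` of thinning
#'   slopes; default `c(F = -0.004, M = -0.005)`.
#' @param sex_offset_mm Additive thickness offset for male scans (mm),
#'   default -0.05 (male cortex slightly thinner at equal age).
#' @param class_effect Named list mapping class to
#'   `list(regions = <integer vector>, effect_mm = <negative scalar>)`.
#'   Defaults emulate mild atrophy in RR and stronger, more extensive atrophy
#'   in the progressive forms; `HC` has no effect. Use
#'   [null_class_effect()] for a no-signal cohort.
#' @param within_patient_sd_mm SD of the per-scan intercept (mm), default 0.05.
#' @param patient_intercept_sd_mm SD of the per-patient intercept (mm),
#'   default 0.05.
#' @param vertex_noise_sd_mm SD of vertex-level noise (mm), default 0.35.
#' @param vertex_noise_skew Skew-normal shape parameter alpha of the vertex
#'   noise (0 = gaussian), default 4.
#' @param sex_ratio Named list mapping class to `c(F = , M = )` patient
#'   counts or proportions; defaults follow the study-scale cohort.
#' @param age_at_entry Named list mapping class to `c(mean, sd)` of the age at
#'   first scan (years); HC uses a uniform range instead (see
#'   `hc_age_range`).
#' @param hc_age_range Age range (years) for healthy-control subjects,
#'   default `c(21.6, 56.5)`.
#' @param age_limits Hard truncation of all simulated ages, default
#'   `c(20, 86)`.
#' @param visit_schedule_years Function mapping a scan index (1-based) to the
#'   years elapsed since the first scan. The default follows a 6-month
#'   interval for the first six scans and yearly visits afterwards.
#' @param seed Integer seed; identical seed + configuration gives
#'   byte-identical output tables.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_healthy_reference()]
#' @export
sim_config <- function(atlas_size = 68L,
                       vertices_per_region = 200L,
                       n_patients_per_class = c(RR = 42L, PP = 21L, SP = 28L, HC = 21L),
                       scans_per_class = c(RR = 299L, PP = 143L, SP = 218L, HC = 21L),
                       scans_per_patient = NULL,
                       baseline_mean_mm = NULL,
                       baseline_range_mm = c(2, 3),
                       healthy_slope_mm_per_year = c(F = -0.004, M = -0.005),
                       sex_offset_mm = -0.05,
                       class_effect = default_class_effect(atlas_size),
                       within_patient_sd_mm = 0.05,
                       patient_intercept_sd_mm = 0.05,
                       vertex_noise_sd_mm = 0.35,
                       vertex_noise_skew = 4,
                       sex_ratio = list(RR = c(F = 30, M = 12), PP = c(F = 12, M = 9),
                                        SP = c(F = 11, M = 17), HC = c(F = 14, M = 7)),
                       age_at_entry = list(RR = c(33, 6), PP = c(41, 5),
                                           SP = c(40, 5), HC = NULL),
                       hc_age_range = c(21.6, 56.5),
                       age_limits = c(20, 86),
                       visit_schedule_years = default_visit_schedule,
                       seed = 1L) {
  classes <- names(n_patients_per_class)
  if (is.null(classes) || !all(classes %in% c("RR", "PP", "SP", "HC"))) {
    stop("n_patients_per_class must be named with classes among RR, PP, SP, HC")
  }
  if (any(n_patients_per_class <= 0)) stop("patient counts must be positive")
  if (!is.null(scans_per_patient)) {
    if (scans_per_patient <= 0) stop("scans_per_patient must be positive")
  } else {
    if (!all(classes %in% names(scans_per_class))) {
      stop("scans_per_class must cover every class in n_patients_per_class")
    }
    if (any(scans_per_class[classes] < n_patients_per_class[classes])) {
      stop("each class needs at least one scan per patient")
    }
  }
  if (atlas_size < 1) stop("atlas_size must be positive")
  if (vertices_per_region < 1) stop("vertices_per_region must be positive")
  if (!all(c("F", "M") %in% names(healthy_slope_mm_per_year))) {
    stop("healthy_slope_mm_per_year needs components F and M")
  }
  bad <- setdiff(names(class_effect), c("RR", "PP", "SP", "HC"))
  if (length(bad)) stop("unknown class key in class_effect: ", paste(bad, collapse = ", "))
  for (cl in names(class_effect)) {
    ce <- class_effect[[cl]]
    if (length(ce$regions) && (max(ce$regions) > atlas_size || min(ce$regions) < 1)) {
      stop("class_effect regions out of range for atlas_size ", atlas_size)
    }
  }
  if (!is.null(baseline_mean_mm) && length(baseline_mean_mm) != atlas_size) {
    stop("baseline_mean_mm must have length atlas_size")
  }
  cfg <- list(
    atlas_size = as.integer(atlas_size),
    vertices_per_region = as.integer(vertices_per_region),
    n_patients_per_class = n_patients_per_class,
    scans_per_class = scans_per_class,
    scans_per_patient = scans_per_patient,
    baseline_mean_mm = baseline_mean_mm,
    baseline_range_mm = baseline_range_mm,
    healthy_slope_mm_per_year = healthy_slope_mm_per_year,
    sex_offset_mm = sex_offset_mm,
    class_effect = class_effect,
    within_patient_sd_mm = within_patient_sd_mm,
    patient_intercept_sd_mm = patient_intercept_sd_mm,
    vertex_noise_sd_mm = vertex_noise_sd_mm,
    vertex_noise_skew = vertex_noise_skew,
    sex_ratio = sex_ratio,
    age_at_entry = age_at_entry,
    hc_age_range = hc_age_range,
    age_limits = age_limits,
    visit_schedule_years = visit_schedule_years,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default per-class regional atrophy pattern
#'
#' Affected region subsets are deterministic, interleaved strides over the
#' atlas so the three forms overlap only partially: RR thins 10% of regions
#' mildly, PP 15% and SP 20% more strongly, reflecting the predominantly
#' neurodegenerative character of the progressive forms.
#'
#' @param n_regions Atlas size N.
#' @return Named list of `list(regions, effect_mm)` per class.
#' @export
default_class_effect <- function(n_regions) {
  pick <- function(frac, offset) {
    k <- max(1L, round(frac * n_regions))
    idx <- (offset + seq_len(k) * floor(n_regions / k) - 1L) %% n_regions + 1L
    sort(unique(idx))
  }
  list(
    RR = list(regions = pick(0.10, 0L), effect_mm = -0.05),
    PP = list(regions = pick(0.15, 1L), effect_mm = -0.10),
    SP = list(regions = pick(0.20, 2L), effect_mm = -0.12),
    HC = list(regions = integer(0), effect_mm = 0)
  )
}

#' Standardized atrophy effect in millimetres
#'
#' Converts a standardized effect size d into millimetres of regional
#' thinning: `d * vertex_noise_sd_mm`. The vertex-level thickness SD is the
#' generator's noise unit, so a one-SD effect shifts an affected region's
#' thickness distribution by one within-region SD.
#'
#' @param config A [sim_config()].
#' @param d Standardized effect size (default 1).
#' @return Effect in mm (negative = thinning).
#' @export
standardized_effect_mm <- function(config, d = 1) {
  -abs(d) * config$vertex_noise_sd_mm
}

#' Class effect with zero atrophy everywhere (null cohort)
#' @return Named list usable as `class_effect` in [sim_config()].
#' @export
null_class_effect <- function() {
  list(RR = list(regions = integer(0), effect_mm = 0),
       PP = list(regions = integer(0), effect_mm = 0),
       SP = list(regions = integer(0), effect_mm = 0),
       HC = list(regions = integer(0), effect_mm = 0))
}

#' Default longitudinal visit schedule
#'
#' Six-month intervals for the first six scans, yearly visits afterwards.
#'
#' @param scan_index 1-based scan index within a patient.
#' @return Years elapsed since the first scan.
#' @export
default_visit_schedule <- function(scan_index) {
  ifelse(scan_index <= 6, (scan_index - 1) * 0.5, 2.5 + (scan_index - 6))
}

# Centered, unit-variance-scaled skew-normal noise.
rskewnorm <- function(n, sd, alpha) {
  if (sd == 0) return(numeric(n))
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(n)
  u1 <- rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  mu_z <- delta * sqrt(2 / pi)
  sd_z <- sqrt(1 - 2 * delta^2 / pi)
  (z - mu_z) / sd_z * sd
}

# Spread `total` scans over `n` patients as evenly as possible.
distribute_scans <- function(total, n) {
  base <- total %/% n
  extra <- total %% n
  base + as.integer(seq_len(n) <= extra)
}

#' Simulate a longitudinal multi-class scan cohort
#'
#' Draws patients per clinical form, assigns each a sex, an entry age, a
#' random intercept and a scan schedule, then generates vertex-level cortical
#' thickness tables per scan under the model documented in [sim_config()].
#'
#' @param config A [sim_config()] object.
#' @return An object of class `scan_cohort`: a list with
#'   \describe{
#'     \item{metadata}{`data.table` with one row per scan: `scan_id`,
#'       `patient_id`, `age_years`, `sex`, `label`.}
#'     \item{thickness}{`data.table` in long format: `scan_id`, `vertex_id`,
#'       `region_id`, `thickness_mm`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cfg <- sim_config(atlas_size = 20, vertices_per_region = 30,
#'                   n_patients_per_class = c(RR = 3, HC = 2),
#'                   scans_per_class = c(RR = 7, HC = 2), seed = 1)
#' coh <- simulate_cohort(cfg)
#' table(coh$metadata$label)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$atlas_size
  baseline <- config$baseline_mean_mm
  if (is.null(baseline)) {
    baseline <- runif(N, config$baseline_range_mm[1], config$baseline_range_mm[2])
  }

  classes <- names(config$n_patients_per_class)
  meta_rows <- list()
  pat_counter <- 0L
  for (cl in classes) {
    n_pat <- config$n_patients_per_class[[cl]]
    if (!is.null(config$scans_per_patient)) {
      n_scans <- rep(config$scans_per_patient, n_pat)
    } else if (cl == "HC") {
      n_scans <- distribute_scans(config$scans_per_class[[cl]], n_pat)
    } else {
      n_scans <- distribute_scans(config$scans_per_class[[cl]], n_pat)
    }
    ratio <- config$sex_ratio[[cl]]
    if (is.null(ratio)) ratio <- c(F = 1, M = 1)
    n_f <- round(n_pat * ratio[["F"]] / sum(ratio))
    sexes <- c(rep("F", n_f), rep("M", n_pat - n_f))
    for (p in seq_len(n_pat)) {
      pat_counter <- pat_counter + 1L
      pid <- sprintf("P%04d", pat_counter)
      ae <- config$age_at_entry[[cl]]
      if (is.null(ae)) {
        age0 <- runif(1, config$hc_age_range[1], config$hc_age_range[2])
      } else {
        age0 <- rnorm(1, ae[1], ae[2])
      }
      age0 <- min(max(age0, config$age_limits[1]), config$age_limits[2])
      u_pat <- rnorm(1, 0, config$patient_intercept_sd_mm)
      idx <- seq_len(n_scans[p])
      ages <- pmin(age0 + config$visit_schedule_years(idx), config$age_limits[2])
      meta_rows[[length(meta_rows) + 1L]] <- data.table::data.table(
        scan_id = sprintf("%s_S%02d", pid, idx),
        patient_id = pid,
        age_years = ages,
        sex = sexes[p],
        label = cl,
        .u_patient = u_pat
      )
    }
  }
  meta <- data.table::rbindlist(meta_rows)

  thickness <- generate_thickness(meta, baseline, config)
  meta[, ".u_patient" := NULL]
  structure(list(metadata = meta, thickness = thickness,
                 config = config, baseline_mean_mm = baseline),
            class = "scan_cohort")
}

# Vertex-level thickness for every scan in `meta` (needs .u_patient column).
generate_thickness <- function(meta, baseline, config) {
  N <- config$atlas_size
  V <- config$vertices_per_region
  n_scan <- nrow(meta)
  slope <- config$healthy_slope_mm_per_year
  class_eff <- lapply(config$class_effect, function(ce) {
    v <- numeric(N)
    if (length(ce$regions)) v[ce$regions] <- ce$effect_mm
    v
  })

  scan_int <- rnorm(n_scan, 0, config$within_patient_sd_mm)
  region_means <- matrix(0, nrow = n_scan, ncol = N)
  for (s in seq_len(n_scan)) {
    cl <- meta$label[s]
    ce <- class_eff[[cl]]
    if (is.null(ce)) ce <- numeric(N)
    region_means[s, ] <- baseline +
      slope[[meta$sex[s]]] * meta$age_years[s] +
      (if (meta$sex[s] == "M") config$sex_offset_mm else 0) +
      ce + meta$.u_patient[s] + scan_int[s]
  }

  noise <- rskewnorm(n_scan * N * V, config$vertex_noise_sd_mm,
                     config$vertex_noise_skew)
  # layout: scan-major, region, vertex
  vals <- rep(as.vector(t(region_means)), each = V) + noise
  vals <- pmax(vals, 0.5)
  data.table::data.table(
    scan_id = rep(meta$scan_id, each = N * V),
    vertex_id = rep.int(seq_len(N * V), n_scan),
    region_id = rep(rep(seq_len(N), each = V), n_scan),
    thickness_mm = vals
  )
}

#' Simulate a healthy reference cohort
#'
#' One scan per subject over a wide age range, as used to fit the age/sex
#' normalization models. Defaults emulate a reference set of 335 scans: 21
#' controls following the patient protocol (ages 21.6-56.5) plus 314 controls
#' from an open population cohort (ages 20.1-86.2).
#'
#' @param config A [sim_config()]; its class effects are ignored (all scans
#'   are HC) and only noise/slope/baseline parameters are used.
#' @param n_subjects Named vector `c(amsep = 21, ixi = 314)` of subject
#'   counts for the two sub-cohorts.
#' @param ixi_age_range Age range of the population sub-cohort, default
#'   `c(20.1, 86.2)`.
#' @param ixi_sex_ratio `c(F = 175, M = 139)` by default.
#' @return A `scan_cohort` whose metadata gains a `cohort` column
#'   (`"AMSEP"` or `"IXI"`).
#' @export
simulate_healthy_reference <- function(config,
                                       n_subjects = c(amsep = 21L, ixi = 314L),
                                       ixi_age_range = c(20.1, 86.2),
                                       ixi_sex_ratio = c(F = 175, M = 139)) {
  stopifnot(inherits(config, "sim_config"))
  if (any(n_subjects <= 0)) stop("subject counts must be positive")
  set.seed(config$seed + 1L)
  N <- config$atlas_size
  baseline <- config$baseline_mean_mm
  if (is.null(baseline)) {
    baseline <- runif(N, config$baseline_range_mm[1], config$baseline_range_mm[2])
  }

  build_group <- function(n, age_range, ratio, tag, offset) {
    n_f <- round(n * ratio[["F"]] / sum(ratio))
    sexes <- c(rep("F", n_f), rep("M", n - n_f))
    ages <- runif(n, age_range[1], age_range[2])
    pid <- sprintf("H%s%04d", tag, offset + seq_len(n))
    data.table::data.table(
      scan_id = paste0(pid, "_S01"),
      patient_id = pid,
      age_years = ages,
      sex = sexes,
      label = "HC",
      cohort = if (tag == "A") "AMSEP" else "IXI",
      .u_patient = rnorm(n, 0, config$patient_intercept_sd_mm)
    )
  }
  meta <- data.table::rbindlist(list(
    build_group(n_subjects[["amsep"]], config$hc_age_range,
                c(F = 14, M = 7), "A", 0L),
    build_group(n_subjects[["ixi"]], ixi_age_range, ixi_sex_ratio, "I", 1000L)
  ))
  thickness <- generate_thickness(meta, baseline, config)
  meta_out <- data.table::copy(meta)[, ".u_patient" := NULL]
  structure(list(metadata = meta_out, thickness = thickness,
                 config = config, baseline_mean_mm = baseline),
            class = "scan_cohort")
}

#' @export
print.scan_cohort <- function(x, ...) {
  cat("scan_cohort:", nrow(x$metadata), "scans,",
      length(unique(x$metadata$patient_id)), "patients,",
      x$config$atlas_size, "regions\n")
  print(table(x$metadata$label))
  invisible(x)
}

#' Write a cohort to TSV files
#'
#' Writes `metadata.tsv` (scan_id, patient_id, age_years, sex, label) and
#' `thickness.tsv` (scan_id, vertex_id, region_id, thickness_mm) into `dir`.
#'
#' @param cohort A `scan_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "scan_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(cohort$metadata, file.path(dir, "metadata.tsv"), sep = "\t")
  data.table::fwrite(cohort$thickness, file.path(dir, "thickness.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory holding `metadata.tsv` and `thickness.tsv`.
#' @return A `scan_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  meta <- data.table::fread(file.path(dir, "metadata.tsv"), sep = "\t")
  thick <- data.table::fread(file.path(dir, "thickness.tsv"), sep = "\t")
  structure(list(metadata = meta, thickness = thick, config = NULL),
            class = "scan_cohort")
}
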