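# Cohort-level synthetic data: published summary statistics of the reference
# cohort (the fixture bank), a subject-table generator reproducing those
# group distributions, and the screening registry that feeds the exclusion
# filter. All draws are seeded and reproducible.

#' Reference cohort summary tables
#'
#' The published group-level summaries of the 169-subject reference cohort
#' that this package's synthetic cohorts emulate and its replay statistics
#' recompute: per-group (n, mean, SD) of the four L1 cortical parameters by
#' age stratum and by vBMD class, the reported ANOVA F statistics, the ROC
#' rows (AUC, Youden cutoff, specificity, sensitivity) for discriminating
#' osteoporosis, the pairwise DeLong comparisons, and the screening flow.
#'
#' Units follow the reported convention: density HU/mm^3, thickness mm,
#' area mm^2, total volume in units of 10^3 mm^3.
#'
#' @return A list of data frames: `age_all`, `age_female`, `age_male`
#'   (parameter x age-stratum summaries with reported F), `bmd_groups`
#'   (parameter x vBMD-class summaries with reported F), `roc` (per study
#'   group and parameter), `delong` (pairwise Z and p), `screening`
#'   (exclusion category counts), `demographics` (sex/stratum/class counts).
#'   Every frame carries a `provenance` attribute `"reported"`.
#' @export
reference_tables <- function() {
  params <- c("average_density", "average_thickness", "average_area", "total_volume")
  mk_summary <- function(groups, n, stats) {
    df <- data.frame(
      parameter = rep(params, each = length(groups)),
      group = rep(groups, times = length(params)),
      n = rep(n, times = length(params)),
      mean = as.vector(t(as.matrix(stats[, c("m1", "m2", "m3")]))),
      sd = as.vector(t(as.matrix(stats[, c("s1", "s2", "s3")]))),
      f_reported = rep(stats$f, each = length(groups)),
      stringsAsFactors = FALSE
    )
    attr(df, "provenance") <- "reported"
    df
  }
  strata <- c("50-59", "60-69", ">=70")

  age_all <- mk_summary(strata, c(71, 55, 43), data.frame(
    m1 = c(432.35, 1.83, 390.63, 10.46), s1 = c(109.70, 0.66, 226.90, 6.31),
    m2 = c(410.11, 1.60, 328.60, 8.37),  s2 = c(91.81, 0.70, 227.18, 6.11),
    m3 = c(431.77, 1.27, 245.05, 6.31),  s3 = c(96.28, 0.68, 169.77, 4.47),
    f  = c(0.885, 9.194, 6.217, 6.944)))

  age_female <- mk_summary(strata, c(29, 23, 21), data.frame(
    m1 = c(437.37, 1.81, 383.13, 10.04), s1 = c(128.00, 0.60, 239.53, 6.42),
    m2 = c(397.26, 1.48, 254.60, 6.20),  s2 = c(93.28, 0.76, 187.96, 4.64),
    m3 = c(427.30, 1.01, 216.85, 5.39),  s3 = c(83.11, 0.62, 192.25, 4.91),
    f  = c(0.956, 8.965, 4.383, 5.292)))

  age_male <- mk_summary(strata, c(42, 32, 22), data.frame(
    m1 = c(428.88, 1.84, 395.80, 10.76), s1 = c(96.58, 0.70, 220.56, 6.30),
    m2 = c(419.36, 1.68, 381.79, 9.94),  s2 = c(91.10, 0.65, 240.51, 6.62),
    m3 = c(436.03, 1.51, 271.97, 7.18),  s3 = c(109.18, 0.65, 144.53, 3.91),
    f  = c(0.198, 1.743, 2.627, 2.643)))

  bmd_groups <- mk_summary(c("normal", "osteopenia", "osteoporosis"),
                           c(59, 58, 52), data.frame(
    m1 = c(446.95, 1.85, 416.75, 11.11), s1 = c(114.98, 0.70, 217.28, 5.87),
    m2 = c(414.49, 1.75, 365.61, 9.56),  s2 = c(94.66, 0.61, 221.03, 6.11),
    m3 = c(411.71, 1.19, 202.91, 5.09),  s3 = c(86.70, 0.63, 159.19, 4.25),
    f  = c(2.200, 16.436, 16.507, 17.482)))

  roc <- data.frame(
    study_group = rep(c("all", "female", "male"), each = 3),
    parameter = rep(c("average_thickness", "average_area", "total_volume"), 3),
    auc = c(0.75, 0.80, 0.80, 0.72, 0.75, 0.76, 0.77, 0.83, 0.84),
    ci_low = c(0.68, 0.73, 0.74, 0.60, 0.64, 0.65, 0.67, 0.74, 0.75),
    ci_high = c(0.81, 0.85, 0.86, 0.82, 0.85, 0.85, 0.85, 0.90, 0.91),
    cutoff = c(1.20, 209.70, 5.49, 1.10, 202.40, 4.46, 1.20, 283.40, 6.00),
    specificity = c(59.62, 71.15, 73.08, 56.25, 75.00, 71.87, 65.00, 90.00, 80.00),
    sensitivity = c(80.34, 83.76, 82.05, 78.05, 78.05, 82.93, 82.89, 69.74, 81.58),
    stringsAsFactors = FALSE)
  attr(roc, "provenance") <- "reported"

  delong <- data.frame(
    study_group = rep(c("all", "female", "male"), each = 3),
    comparison = rep(c("thickness_vs_area", "thickness_vs_volume", "area_vs_volume"), 3),
    z = c(1.064, 1.224, 1.382, 0.548, 0.652, 0.955, 0.884, 1.003, 0.826),
    p = c(0.287, 0.221, 0.167, 0.584, 0.515, 0.339, 0.377, 0.316, 0.409),
    stringsAsFactors = FALSE)
  attr(delong, "provenance") <- "reported"

  screening <- data.frame(
    category = c("spinal_fracture_or_tumor", "bone_metabolic_disease_or_drugs",
                 "spinal_surgery", "unqualified_image_quality",
                 "incomplete_L1_L2_coverage"),
    n_excluded = c(32, 45, 21, 38, 21),
    stringsAsFactors = FALSE)
  attr(screening, "provenance") <- "reported"

  demographics <- list(
    n_screened = 326L, n_excluded = 157L, n_included = 169L,
    n_male = 96L, n_female = 73L,
    age_mean = 63.23, age_sd = 8.41, age_range = c(50L, 87L),
    strata_all = c("50-59" = 71L, "60-69" = 55L, ">=70" = 43L),
    strata_female = c("50-59" = 29L, "60-69" = 23L, ">=70" = 21L),
    strata_male = c("50-59" = 42L, "60-69" = 32L, ">=70" = 22L),
    bmd_all = c(normal = 59L, osteopenia = 58L, osteoporosis = 52L),
    op_female = 32L, nonop_female = 41L, op_male = 20L, nonop_male = 76L)

  list(age_all = age_all, age_female = age_female, age_male = age_male,
       bmd_groups = bmd_groups, roc = roc, delong = delong,
       screening = screening, demographics = demographics)
}

#' Cohort generation specification
#'
#' Defines the group structure from which [generate_cohort()] draws subject
#' records. Defaults are the reference cohort's vBMD-class summaries (group
#' sizes 59/58/52) with sex and age-stratum margins matching the reported
#' counts.
#'
#' @param groups data frame with columns `parameter`, `group`, `n`, `mean`,
#'   `sd` (long format, one row per parameter x group); default
#'   `reference_tables()$bmd_groups`.
#' @param rank_correlation within-subject correlation of the Gaussian copula
#'   linking thickness, area and volume (default 0.6); density is coupled at
#'   `rank_correlation / 3`.
#' @param truncation_floor physically positive parameters are re-floored at
#'   this value (in the parameter's own unit) when a Gaussian draw is
#'   negative; the record is flagged `truncated`. Default 0.01.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = reference_tables()$bmd_groups,
                        rank_correlation = 0.6,
                        truncation_floor = 0.01,
                        seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("parameter", "group", "n", "mean", "sd") %in% names(groups)),
            nrow(groups) > 0, all(groups$n >= 1), all(groups$sd >= 0),
            rank_correlation >= 0, rank_correlation < 1,
            truncation_floor > 0)
  structure(list(groups = groups, rank_correlation = rank_correlation,
                 truncation_floor = truncation_floor, seed = as.integer(seed)),
            class = "cohort_spec")
}

# vBMD sampling windows per class (mg/cm^3); means/SDs are a modelling
# choice, truncated to the class-defining windows (normal > 120,
# osteopenia [80, 120], osteoporosis < 80).
VBMD_MODEL <- list(
  normal = list(mean = 145, sd = 20, lo = 120.5, hi = 220),
  osteopenia = list(mean = 100, sd = 11, lo = 80, hi = 120),
  osteoporosis = list(mean = 62, sd = 14, lo = 20, hi = 79.5))

draw_truncnorm <- function(n, mean, sd, lo, hi) {
  # inverse-CDF truncated normal; exact, vectorizes, seed-stable
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic subject cohort
#'
#' Draws one record per subject: the four cortical parameters from per-group
#' Gaussians with the spec's means/SDs coupled by a Gaussian copula, a vBMD
#' value consistent with the group label, and (when the default three-class
#' structure is used) sex and age allocated so the sex x age-stratum margins
#' reproduce the reference cohort counts. Negative draws of physically
#' positive quantities are floored at `truncation_floor` and flagged.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with one row per subject: `subject_id`, `sex`, `age`,
#'   `age_stratum`, `bmd_group`, `vbmd`, the four parameters
#'   (`average_density` HU/mm^3, `average_thickness` mm, `average_area`
#'   mm^2, `total_volume` 10^3 mm^3), and `truncated`.
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 42))
#' table(coh$bmd_group)   # 59 / 58 / 52
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$groups
  group_labels <- unique(g$group)
  params <- unique(g$parameter)
  npar <- length(params)

  # copula correlation: block of rank_correlation among structural
  # parameters, weaker coupling to density
  R <- matrix(spec$rank_correlation, npar, npar)
  diag(R) <- 1
  if ("average_density" %in% params) {
    i <- which(params == "average_density")
    R[i, -i] <- R[-i, i] <- spec$rank_correlation / 3
  }
  L <- chol(R)

  with_seed(spec$seed, {
    rows <- lapply(group_labels, function(lab) {
      gg <- g[g$group == lab, ]
      n <- gg$n[1]
      Z <- matrix(stats::rnorm(n * npar), n, npar) %*% L
      vals <- sapply(seq_len(npar), function(j) {
        r <- gg[gg$parameter == params[j], ]
        r$mean + Z[, j] * r$sd
      })
      vals <- matrix(vals, n, npar, dimnames = list(NULL, params))
      truncated <- apply(vals < spec$truncation_floor, 1, any)
      vals[vals < spec$truncation_floor] <- spec$truncation_floor
      out <- as.data.frame(vals)
      out$bmd_group <- lab
      out$truncated <- truncated
      if (lab %in% names(VBMD_MODEL)) {
        vm <- VBMD_MODEL[[lab]]
        out$vbmd <- draw_truncnorm(n, vm$mean, vm$sd, vm$lo, vm$hi)
      } else out$vbmd <- NA_real_
      out
    })
    coh <- do.call(rbind, rows)

    if (setequal(group_labels, c("normal", "osteopenia", "osteoporosis")) &&
        identical(unname(sapply(rows, nrow)), c(59L, 58L, 52L))) {
      coh <- cbind(coh, allocate_demographics())
    } else {
      coh$sex <- NA_character_; coh$age <- NA_real_
      coh$age_stratum <- NA_character_
    }
    coh$subject_id <- sprintf("S%03d", seq_len(nrow(coh)))
    rownames(coh) <- NULL
    coh[, c("subject_id", "sex", "age", "age_stratum", "bmd_group", "vbmd",
            params, "truncated")]
  })
}

# Joint sex x age x bmd-class allocation matching all reported margins:
# strata 71/55/43 (29/23/21 female, 42/32/22 male), OP counts 32 female /
# 20 male; the unreported normal/osteopenia split per sex is taken
# proportional (female 20/21, male 39/37). Rows are ordered by bmd class
# (59 normal, 58 osteopenia, 52 osteoporosis) to align with generate_cohort.
allocate_demographics <- function() {
  cells <- expand.grid(sex = c("female", "male"),
                       stratum = c("50-59", "60-69", ">=70"),
                       stringsAsFactors = FALSE)
  cells$n <- c(29, 42, 23, 32, 21, 22)
  # per-sex class totals
  class_by_sex <- list(
    female = c(normal = 20, osteopenia = 21, osteoporosis = 32),
    male = c(normal = 39, osteopenia = 37, osteoporosis = 20))
  out <- data.frame(sex = character(0), age = numeric(0),
                    age_stratum = character(0), class = character(0))
  for (sx in c("female", "male")) {
    cls <- class_by_sex[[sx]]
    labels <- rep(names(cls), cls)
    labels <- sample(labels)              # random class-stratum coupling
    strata <- cells[cells$sex == sx, ]
    strat_vec <- rep(strata$stratum, strata$n)
    ages <- unlist(lapply(strata$stratum, function(s) {
      n <- strata$n[strata$stratum == s]
      lo <- switch(s, "50-59" = 50, "60-69" = 60, ">=70" = 70)
      hi <- switch(s, "50-59" = 59, "60-69" = 69, ">=70" = 87)
      sample(lo:hi, n, replace = TRUE)
    }))
    out <- rbind(out, data.frame(sex = sx, age = ages, age_stratum = strat_vec,
                                 class = labels))
  }
  # order rows by class to align with the group-blocked parameter draws
  out <- out[order(match(out$class, c("normal", "osteopenia", "osteoporosis"))), ]
  rownames(out) <- NULL
  out[, c("sex", "age", "age_stratum")]
}

#' Generate the screening registry with exclusion flags
#'
#' Emits the 326-subject screening registry: 157 subjects carry exactly one
#' of five mutually exclusive exclusion-category flags with the reported
#' per-category counts (32 spinal fracture/tumor, 45 bone-metabolic disease
#' or anti-osteoporosis drugs, 21 spinal surgery, 38 unqualified image
#' quality, 21 incomplete L1/L2 coverage); the remaining 169 are eligible.
#' Row order is shuffled deterministically by `seed`.
#'
#' @param seed integer RNG seed.
#' @return data frame with `subject_id`, `excluded` (logical) and
#'   `exclusion_category` (NA for eligible records).
#' @export
generate_screening_registry <- function(seed = 1L) {
  scr <- reference_tables()$screening
  demo <- reference_tables()$demographics
  cats <- c(rep(NA_character_, demo$n_included),
            rep(scr$category, scr$n_excluded))
  with_seed(seed, {
    cats <- sample(cats)
    data.frame(subject_id = sprintf("R%03d", seq_along(cats)),
               excluded = !is.na(cats),
               exclusion_category = cats,
               stringsAsFactors = FALSE)
  })
}

#' Write a subject or registry table as CSV with a JSON parameter sidecar
#'
#' @param df data frame to write.
#' @param path CSV path; the sidecar goes to `<path>.json`.
#' @param params list of generation parameters echoed to the sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(df, path, params = list()) {
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
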