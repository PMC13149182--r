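# Independent oracles and shared fixtures. Oracles deliberately avoid the
# package code paths they check.

# AUC by trapezoidal integration of the empirical ROC curve (oracle for the
# Mann-Whitney identity).
auc_trapezoid <- function(scores, labels, orientation = "lower") {
  labels <- as.logical(labels)
  s <- if (orientation == "lower") -scores else scores
  th <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(s[labels] >= t), 0)
  fpr <- vapply(th, function(t) mean(s[!labels] >= t), 0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Continuous-geometry thickness oracle: length of the outermost shell
# crossing along a ray from the center, by dense sampling of the exact
# ellipse indicator (0.002 mm grid), independent of mask voxelization.
oracle_ray_thickness <- function(a, b, t, angle, step = 0.002) {
  r <- seq(0, max(a, b) + 1, by = step)
  x <- r * cos(angle); y <- r * sin(angle)
  shell <- ((x / a)^2 + (y / b)^2 <= 1) &
           !((x / (a - t))^2 + (y / (b - t))^2 <= 1)
  runs <- rle(shell)
  if (!any(runs$values)) return(NA_real_)
  runs$lengths[max(which(runs$values))] * step
}

# one shared default phantom per test run (noiseless, blur-free)
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_spec(seed = 11))
    cache
  }
})

default_segmentation <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- segment_vertebra(default_phantom()$volume, segmentation_config())
    cache
  }
})

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

random_group_data <- function(k = 3, n_range = c(5, 40)) {
  lapply(seq_len(k), function(i)
    stats::rnorm(sample(n_range[1]:n_range[2], 1),
                 mean = stats::runif(1, -2, 2),
                 sd = stats::runif(1, 0.2, 3)))
}

summarize_groups <- function(groups) {
  data.frame(group = paste0("g", seq_along(groups)),
             n = lengths(groups),
             mean = vapply(groups, mean, 0),
             sd = vapply(groups, stats::sd, 0))
}
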