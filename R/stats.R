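#' Convert an area to its linear measurement
#'
#' Areas are linearized (square root, mm) before log transformation in all
#' allometric fits, so that slopes are comparable with linear body-size
#' proxies like ITD.
#'
#' @param area_mm2 nonnegative area(s) in mm^2.
#' @return sqrt(area) in mm.
#' @export
linearize_area <- function(area_mm2) {
  if (any(area_mm2 < 0)) abort("area must be nonnegative")
  sqrt(area_mm2)
}

#' Log-log allometric regression against ITD
#'
#' Ordinary least squares of `log(sqrt(area))` on `log(ITD)` with a
#' two-sided t test on the slope (df = n - 2). A reduced-major-axis slope
#' is available via `method = "rma"` for allometry purists; OLS is the
#' default as it reproduces t statistics of the conventional form.
#'
#' @param itd_mm positive vector of inter-tegular distances (mm).
#' @param area_mm2 positive vector of areas (mm^2), same length.
#' @param method `"ols"` (default) or `"rma"`.
#' @return object of class `dra_allometry` with `slope`, `intercept`,
#'   `slope_se`, `t_stat`, `df`, `p_value`, `n`, `r_squared` and the
#'   underlying data; supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_allometry <- function(itd_mm, area_mm2, method = c("ols", "rma")) {
  method <- match.arg(method)
  if (length(itd_mm) != length(area_mm2))
    abort("itd_mm and area_mm2 must have the same length")
  keep <- is.finite(itd_mm) & is.finite(area_mm2)
  itd_mm <- itd_mm[keep]; area_mm2 <- area_mm2[keep]
  if (length(itd_mm) < 3) abort("insufficient data: need at least 3 specimens")
  if (any(itd_mm <= 0) || any(area_mm2 <= 0))
    abort("itd and area must be positive for the log-log fit")
  x <- log(itd_mm)
  y <- log(linearize_area(area_mm2))
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  slope <- unname(coef(fit)[2])
  slope_se <- sm$coefficients[2, 2]
  t_stat <- sm$coefficients[2, 3]
  p <- sm$coefficients[2, 4]
  if (!is.finite(t_stat) && slope == 0) {  # flat response, zero residual
    t_stat <- 0
    p <- 1
  }
  if (method == "rma") {
    slope <- sign(stats::cor(x, y)) * sd(y) / sd(x)
  }
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         slope_se = slope_se, t_stat = t_stat,
         df = fit$df.residual, p_value = p, n = length(x),
         r_squared = sm$r.squared, method = method, model = fit,
         data = tibble(itd_mm = itd_mm, area_mm2 = area_mm2,
                       log_itd = x, log_sqrt_area = y)),
    class = "dra_allometry"
  )
}

#' @export
print.dra_allometry <- function(x, ...) {
  cat("<dra_allometry> log(sqrt(area)) ~ log(ITD), ", x$method, ", n = ",
      x$n, "\n", sep = "")
  cat(sprintf("  slope %.4f (se %.4f), t(%d) = %.4f, p = %.4g, R^2 = %.3f\n",
              x$slope, x$slope_se, x$df, x$t_stat, x$p_value, x$r_squared))
  invisible(x)
}

#' @export
tidy.dra_allometry <- function(x, ...) {
  sm <- suppressWarnings(summary(x$model))
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(sm$coefficients[1, 2], x$slope_se),
    statistic = c(sm$coefficients[1, 3], x$t_stat),
    p.value = c(sm$coefficients[1, 4], x$p_value)
  )
}

#' @export
glance.dra_allometry <- function(x, ...) {
  tibble(slope = x$slope, slope_se = x$slope_se, t_stat = x$t_stat,
         df = x$df, p.value = x$p_value, r.squared = x$r_squared, n = x$n,
         method = x$method)
}

# Exact null distribution of the signed-rank statistic W+ for the given
# |difference| ranks, by convolution over sign assignments (equivalent to
# enumerating all 2^n sign vectors). Ranks may be midranks; the grid is
# doubled so tied half-ranks stay on integers.
signed_rank_exact_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1)  # probabilities of 2*W on 0..total
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), dist[seq_len(total + 1 - r)])
    dist <- (dist + shifted) / 2
  }
  w2 <- round(2 * w)
  p_le <- sum(dist[seq_len(w2 + 1)])
  p_ge <- sum(dist[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences. Zero differences are dropped and
#' their count reported (the classical treatment). For 15 or fewer nonzero
#' pairs the two-sided p-value is exact, from the full distribution of the
#' statistic over all 2^n sign assignments (ties handled via midranks); for
#' larger samples a tie-corrected normal approximation is used. The normal
#' z statistic is reported alongside W in both cases.
#'
#' @param a,b paired numeric vectors of equal length (>= 2).
#' @param exact_max_n largest n for the exact enumeration (default 15).
#' @return object of class `dra_comparison` with `statistic` (W, the sum of
#'   ranks of positive differences), `z`, `p_value`, `n_used`, `n_zero`.
#' @export
paired_signed_rank <- function(a, b, exact_max_n = 15) {
  if (length(a) != length(b)) abort("a and b must have the same length")
  if (length(a) < 2) abort("need at least 2 pairs")
  d <- a - b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    res <- list(test_name = "signed_rank", statistic = 0, z = 0, p_value = 1,
                n_used = 0L, n_zero = n_zero, method = "degenerate")
    return(structure(res, class = "dra_comparison"))
  }
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sig2 > 0) (w - mu) / sqrt(sig2) else 0
  if (n <= exact_max_n) {
    p <- signed_rank_exact_p(w, rk)
    method <- "exact"
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  structure(
    list(test_name = "signed_rank", statistic = w, z = z, p_value = p,
         n_used = n, n_zero = n_zero, method = method),
    class = "dra_comparison"
  )
}

#' @export
print.dra_comparison <- function(x, ...) {
  cat("<dra_comparison> ", x$test_name, " (", x$method, ")\n", sep = "")
  cat(sprintf("  W = %.3g, z = %.4f, p = %.4g (n = %d, %d zero pairs dropped)\n",
              x$statistic, x$z, x$p_value, x$n_used, x$n_zero))
  invisible(x)
}

#' @export
tidy.dra_comparison <- function(x, ...) {
  tibble(test = x$test_name, statistic = x$statistic, z = x$z,
         p.value = x$p_value, n = x$n_used, n_zero = x$n_zero,
         method = x$method)
}

# Compact letter display: regions sharing a letter are not significantly
# different at alpha. Letters come from the maximal cliques of the
# "not significantly different" graph.
letter_groups <- function(groups, pair_tbl, alpha) {
  g <- igraph::make_empty_graph(n = length(groups), directed = FALSE)
  igraph::V(g)$name <- groups
  ns <- pair_tbl[is.na(pair_tbl$p_adj) | pair_tbl$p_adj >= alpha, , drop = FALSE]
  if (nrow(ns) > 0)
    g <- igraph::add_edges(g, rbind(match(ns$group1, groups),
                                    match(ns$group2, groups)))
  cliques <- igraph::max_cliques(g)
  # order cliques by the smallest member index for stable letters
  ord <- order(vapply(cliques, min, numeric(1)))
  letters_out <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(ord)) {
    members <- groups[as.integer(cliques[[ord[k]]])]
    letters_out[members] <- paste0(letters_out[members], letters[k])
  }
  tibble(region = groups,
         letters = vapply(letters_out, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""), character(1)))
}

#' Compare an ommatidial structure across eye regions
#'
#' Kruskal-Wallis test (tie-corrected H) across the regions present,
#' followed by pairwise Wilcoxon rank-sum tests with Holm adjustment
#' (configurable, including `"none"`), and a compact letter display in
#' which matching letters indicate no significant difference. By default
#' measurements are pooled to one mean per specimen and region before
#' testing, reflecting the eye as the unit of replication.
#'
#' @param measurements tidy measurement table with columns `specimen_id`,
#'   `region`, `structure`, `dimension`, `value_um` (as produced by the
#'   virtual-histology module or [simulate_ommatidial_measurements()]).
#' @param structure,dimension which measurement to compare (e.g. `"cone"`,
#'   `"thickness"`).
#' @param alpha significance level for the letter display.
#' @param adjust p adjustment for the pairwise tests (`"holm"` or
#'   `"none"`).
#' @param pool_specimens average to one value per specimen x region first
#'   (default `TRUE`).
#' @return object of class `dra_region_comparison` with elements `kw`
#'   (statistic, df, p), `pairwise` (tibble), `letters` (tibble);
#'   supports [tidy()], [glance()] and [autoplot()].
#' @export
region_comparison <- function(measurements, structure, dimension = "thickness",
                              alpha = 0.05, adjust = c("holm", "none"),
                              pool_specimens = TRUE) {
  adjust <- match.arg(adjust)
  tab <- dplyr::filter(as_tibble(measurements),
                       .data$structure == !!structure,
                       .data$dimension == !!dimension)
  if (nrow(tab) == 0) abort("no measurements for this structure/dimension")
  if (pool_specimens) {
    tab <- dplyr::summarise(
      dplyr::group_by(tab, .data$specimen_id, .data$region),
      value_um = mean(.data$value_um), .groups = "drop")
  }
  counts <- table(tab$region)
  usable <- names(counts)[counts >= 2]
  if (length(usable) < 2)
    abort("need at least 2 regions with at least 2 values each")
  dropped <- setdiff(names(counts), usable)
  if (length(dropped) > 0)
    warn(paste("regions with fewer than 2 values skipped:",
               paste(dropped, collapse = ", ")))
  tab <- tab[tab$region %in% usable, , drop = FALSE]
  kw <- kruskal.test(tab$value_um, factor(tab$region))
  pairs <- utils::combn(sort(usable), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    wt <- suppressWarnings(
      wilcox.test(tab$value_um[tab$region == g1],
                  tab$value_um[tab$region == g2]))
    tibble(group1 = g1, group2 = g2,
           statistic = unname(wt$statistic), p_raw = wt$p.value)
  })
  pw$p_adj <- p.adjust(pw$p_raw, method = if (adjust == "none") "none" else "holm")
  lett <- letter_groups(sort(usable), pw, alpha)
  structure(
    list(test_name = "kruskal_wallis",
         kw = list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                   p_value = kw$p.value),
         pairwise = pw, letters = lett, alpha = alpha, adjustment = adjust,
         pooled = pool_specimens, structure = structure,
         dimension = dimension, data = tab),
    class = "dra_region_comparison"
  )
}

#' @export
print.dra_region_comparison <- function(x, ...) {
  cat("<dra_region_comparison> ", x$structure, " ", x$dimension,
      if (x$pooled) " (specimen-pooled)" else "", "\n", sep = "")
  cat(sprintf("  Kruskal-Wallis H(%d) = %.4f, p = %.4g\n",
              x$kw$df, x$kw$statistic, x$kw$p_value))
  cat("  pairwise Wilcoxon rank sum (", x$adjustment, "):\n", sep = "")
  for (k in seq_len(nrow(x$pairwise))) {
    cat(sprintf("    %s vs %s: W = %g, p = %.4g\n",
                x$pairwise$group1[k], x$pairwise$group2[k],
                x$pairwise$statistic[k], x$pairwise$p_adj[k]))
  }
  cat("  groups:", paste(x$letters$region, x$letters$letters,
                         sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' @export
tidy.dra_region_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, adjustment = x$adjustment)
}

#' @export
glance.dra_region_comparison <- function(x, ...) {
  tibble(statistic = x$kw$statistic, df = x$kw$df, p.value = x$kw$p_value,
         n = nrow(x$data), pooled = x$pooled)
}
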