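#' Assemble a per-cell population table
#'
#' Validates and normalizes per-cell records for population statistics:
#' requires `group`, `area_um2`, `eccentricity`, `ri` and `rate_amol_min`
#' columns; rows carrying NA in any of those are flagged in a `qc` column
#' (existing flags are preserved) rather than dropped.
#'
#' @param df Data frame of per-cell measurements.
#' @param groups Allowed group labels.
#' @return The validated data frame, class `population_table`.
#' @export
population_table <- function(df, groups = c("-PMA", "+PMA")) {
  need <- c("group", "area_um2", "eccentricity", "ri", "rate_amol_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$group %in% groups))
    stop("group labels outside the allowed set: ",
         paste(setdiff(unique(df$group), groups), collapse = ", "))
  bad <- !stats::complete.cases(df[, setdiff(need, "group")])
  if (!"qc" %in% names(df)) df$qc <- ""
  df$qc[bad & df$qc == ""] <- "incomplete"
  class(df) <- c("population_table", class(df))
  df
}

# KDE mode (argmax of a Gaussian kernel density, Silverman bandwidth)
kde_mode <- function(x) {
  if (length(unique(x)) == 1) return(x[1])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Per-group population summary
#'
#' Means, sample standard deviations (n-1), variances, medians and KDE
#' modes (Silverman bandwidth) of each variable, plus the fraction of cells
#' above a high-efflux threshold.
#'
#' @param table A [population_table()] (QC-flagged rows are excluded).
#' @param variables Columns to summarize.
#' @param high_threshold High-efflux threshold in attomole/cell/min
#'   (default 1000, the hyperactive-outlier boundary).
#' @return Data frame with one row per (group, variable): `n`, `mean`, `sd`,
#'   `var`, `median`, `mode`; attribute `high_efflux` holds the per-group
#'   fractions.
#' @export
summarize_population <- function(table,
                                 variables = c("area_um2", "eccentricity",
                                               "ri", "rate_amol_min"),
                                 high_threshold = 1000) {
  df <- as.data.frame(table)
  if ("qc" %in% names(df)) df <- df[df$qc == "", ]
  if (!nrow(df)) stop("no unflagged rows to summarize")
  out <- list(); he <- list()
  for (gr in unique(df$group)) {
    sub <- df[df$group == gr, ]
    if (nrow(sub) < 2) stop("group ", gr, " has fewer than 2 rows")
    for (v in variables) {
      x <- sub[[v]]
      out[[length(out) + 1]] <- data.frame(
        group = gr, variable = v, n = length(x), mean = mean(x),
        sd = stats::sd(x), var = stats::var(x),
        median = stats::median(x), mode = kde_mode(x))
    }
    he[[gr]] <- mean(sub$rate_amol_min > high_threshold)
  }
  res <- do.call(rbind, out)
  attr(res, "high_efflux") <- unlist(he)
  attr(res, "high_threshold") <- high_threshold
  res
}

#' Compare two groups
#'
#' Percent changes ((B - A)/A * 100) of the group means, variances and
#' high-efflux fractions for each variable, with seeded bootstrap confidence
#' intervals.
#'
#' @param table A [population_table()] containing both groups.
#' @param group_a,group_b Group labels (A is the reference).
#' @param variables Columns to compare.
#' @param high_threshold High-efflux threshold (attomole/cell/min).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Bootstrap seed.
#' @param conf Confidence level.
#' @return Data frame with `variable`, `metric` (`mean`, `var` or
#'   `high_fraction`), `value_a`, `value_b`, `change_pct`, `ci_lo`, `ci_hi`.
#'   A zero reference value yields `NA` change with metric flagged
#'   `"undefined"` in `note`.
#' @export
compare_groups <- function(table, group_a = "-PMA", group_b = "+PMA",
                           variables = c("area_um2", "eccentricity", "ri",
                                         "rate_amol_min"),
                           high_threshold = 1000, n_boot = 2000, seed = 1,
                           conf = 0.95) {
  df <- as.data.frame(table)
  if ("qc" %in% names(df)) df <- df[df$qc == "", ]
  a <- df[df$group == group_a, ]; b <- df[df$group == group_b, ]
  if (!nrow(a) || !nrow(b)) stop("both groups must be present")
  stats_fun <- function(xa, xb, metric, v) {
    fa <- switch(metric, mean = mean(xa), var = stats::var(xa),
                 high_fraction = mean(xa > high_threshold))
    fb <- switch(metric, mean = mean(xb), var = stats::var(xb),
                 high_fraction = mean(xb > high_threshold))
    c(fa, fb)
  }
  rows <- list()
  withr::with_seed(seed, {
    for (v in variables) {
      metrics <- if (v == "rate_amol_min") c("mean", "var", "high_fraction")
                 else c("mean", "var")
      for (m in metrics) {
        xa <- a[[v]]; xb <- b[[v]]
        vals <- stats_fun(xa, xb, m, v)
        change <- if (abs(vals[1]) < .Machine$double.eps) NA_real_
                  else (vals[2] - vals[1]) / vals[1] * 100
        boots <- replicate(n_boot, {
          ra <- xa[sample.int(length(xa), replace = TRUE)]
          rb <- xb[sample.int(length(xb), replace = TRUE)]
          bv <- stats_fun(ra, rb, m, v)
          if (abs(bv[1]) < .Machine$double.eps) NA_real_
          else (bv[2] - bv[1]) / bv[1] * 100
        })
        qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                              na.rm = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, metric = m, value_a = vals[1], value_b = vals[2],
          change_pct = change, ci_lo = qs[1], ci_hi = qs[2],
          note = if (is.na(change)) "undefined" else "")
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect bimodality by Gaussian-mixture BIC comparison
#'
#' Fits 1- and 2-component Gaussian mixtures (equal- and unequal-variance)
#' and declares bimodality when the 2-component BIC exceeds the 1-component
#' BIC by more than `delta_bic` (default 6, strong evidence on the
#' Kass-Raftery scale).
#'
#' @param values Numeric vector, `n >= 50`.
#' @param delta_bic Decision threshold on the BIC difference.
#' @return List with `is_bimodal`, `delta_bic`, `means`, `sds`, `weights`
#'   (of the 2-component fit) and `flag` (`"degenerate"` when the mixture
#'   fit failed, in which case the call is unimodal).
#' @export
detect_bimodality <- function(values, delta_bic = 6) {
  values <- values[is.finite(values)]
  if (length(values) < 50) stop("need at least 50 values")
  # Mclust evaluates its BIC call in the caller's frame; bind the helper
  # locally so the package works without mclust on the search path
  mclustBIC <- mclust::mclustBIC
  b1 <- mclust::Mclust(values, G = 1, verbose = FALSE)
  b2 <- tryCatch(mclust::Mclust(values, G = 2, modelNames = c("E", "V"),
                                verbose = FALSE),
                 error = function(e) NULL)
  if (is.null(b2) || is.null(b2$bic) || !is.finite(b2$bic))
    return(list(is_bimodal = FALSE, delta_bic = NA_real_, means = NA,
                sds = NA, weights = NA, flag = "degenerate"))
  dbic <- as.numeric(b2$bic) - as.numeric(b1$bic)
  par <- b2$parameters
  sds <- sqrt(if (length(par$variance$sigmasq) == 1)
    rep(par$variance$sigmasq, 2) else par$variance$sigmasq)
  list(is_bimodal = dbic > delta_bic, delta_bic = dbic,
       means = as.numeric(par$mean), sds = sds,
       weights = as.numeric(par$pro), flag = "")
}

#' Two-dimensional kernel density estimate
#'
#' Product-kernel Gaussian KDE on an `n x n` grid spanning the data plus
#' three bandwidths, normalized to integrate to 1.
#'
#' @param x,y Paired finite observations, `n >= 10`.
#' @param n Grid side length (default 128).
#' @return List with `x`, `y` (grid axes) and `z` (density matrix).
#' @export
kde2d_grid <- function(x, y, n = 128) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10) stop("need at least 10 paired observations")
  hx <- MASS::bandwidth.nrd(x); hy <- MASS::bandwidth.nrd(y)
  if (hx <= 0 || hy <= 0) stop("degenerate bandwidth")
  lims <- c(range(x) + c(-0.75, 0.75) * hx,
            range(y) + c(-0.75, 0.75) * hy)   # +/- 3 kernel sd (h/4)
  d <- MASS::kde2d(x, y, h = c(hx, hy), n = n, lims = lims)
  cellw <- diff(d$x[1:2]) * diff(d$y[1:2])
  d$z <- d$z / (sum(d$z) * cellw)
  d
}
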