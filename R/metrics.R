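#' Temporal signal-to-noise ratio
#'
#' ROI-level TSNR of a set of per-pair MBF maps: the mask-mean MBF of
#' each map is computed, and TSNR is the mean of those values divided by
#' their sample (n-1) standard deviation. When the SD is zero the result
#' is flagged undefined (`NaN` with attribute `defined = FALSE`), never
#' infinite. `mode = "pixel"` instead forms the per-pixel mean/SD ratio
#' across maps and returns its median over the mask (a secondary,
#' per-pixel reading of the same statistic).
#'
#' Only pixels valid in every map contribute.
#'
#' @param maps list of [MBFMap-class]s (or numeric matrices) on one grid.
#' @param mask logical analysis mask; default the first map's myocardial
#'   mask.
#' @param mode `"roi"` (default) or `"pixel"`.
#' @return TSNR as a single number; attribute `defined` is `FALSE` when
#'   the SD was zero.
#' @examples
#' maps <- lapply(seq(1, 2, 0.2), function(v) matrix(v, 2, 2))
#' tsnr(maps, matrix(TRUE, 2, 2))  # 4.009
#' @export
tsnr <- function(maps, mask = NULL, mode = c("roi", "pixel")) {
  mode <- match.arg(mode)
  asVals <- function(m) if (is(m, "MBFMap")) m@values else m
  asValid <- function(m) if (is(m, "MBFMap")) m@validMask else
    matrix(TRUE, nrow(m), ncol(m))
  vals <- lapply(maps, asVals)
  if (is.null(mask)) {
    stopifnot(is(maps[[1]], "MBFMap"))
    mask <- maps[[1]]@myoMask
  }
  valid <- Reduce(`&`, lapply(maps, asValid))
  mask <- mask & valid
  stopifnot(any(mask))
  if (mode == "roi") {
    means <- vapply(vals, function(v) mean(v[mask]), numeric(1))
    s <- stats::sd(means)
    if (s == 0) return(structure(NaN, defined = FALSE))
    structure(mean(means) / s, defined = TRUE)
  } else {
    stack <- vapply(vals, function(v) v[mask], numeric(sum(mask)))
    mu <- rowMeans(stack)
    s <- apply(stack, 1, stats::sd)
    ok <- s > 0
    if (!any(ok)) return(structure(NaN, defined = FALSE))
    structure(stats::median(mu[ok] / s[ok]), defined = TRUE)
  }
}

# Paired t-test p-value robust to degenerate (zero-variance) differences:
# identical pairs -> p = 1; a constant nonzero shift -> p = 0.
pairedTP <- function(x, y) {
  d <- x - y
  if (stats::sd(d) == 0) return(if (all(d == 0)) 1 else 0)
  stats::t.test(x, y, paired = TRUE)$p.value
}

#' Compare protocols with one-way ANOVA and paired post-hoc t-tests
#'
#' One-way (unpaired) ANOVA of the chosen metric across protocols. When
#' the ANOVA rejects at `alpha`, two-tailed paired t-tests (paired by
#' subject, since every subject undergoes every protocol) are run for
#' all protocol pairs at the same threshold, without multiplicity
#' correction. The design must be complete: a missing
#' (subject, protocol) cell is an error naming the cell.
#'
#' @param results data.frame with columns `subject`, `protocol` and the
#'   metric column; at least two subjects.
#' @param metric name of the metric column (e.g. `"mean_mbf"`, `"tsnr"`,
#'   `"n_pixels"`).
#' @param alpha significance threshold.
#' @return a [ComparisonReport-class].
#' @examples
#' df <- data.frame(subject = rep(1:3, 3),
#'                  protocol = rep(c("A", "B", "C"), each = 3),
#'                  y = c(1, 2, 3, 2, 3, 4, 6, 7, 8))
#' compareMethods(df, "y")  # F = 21
#' @export
compareMethods <- function(results, metric, alpha = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("subject", "protocol", metric) %in% names(results)))
  subjects <- unique(results$subject)
  protocols <- unique(results$protocol)
  if (length(subjects) < 2) stop("at least two subjects are required")
  grid <- expand.grid(subject = subjects, protocol = protocols)
  key <- paste(results$subject, results$protocol)
  missing <- grid[!paste(grid$subject, grid$protocol) %in% key, ]
  if (nrow(missing))
    stop("missing cell(s): ",
         paste(sprintf("(subject %s, protocol %s)",
                       missing$subject, missing$protocol), collapse = ", "))
  y <- results[[metric]]
  g <- factor(results$protocol)
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (is.na(Fv)) { Fv <- 0; p <- 1 }  # zero residual + zero group variance
  groupStats <- do.call(rbind, lapply(split(y, g), function(x)
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x))))
  groupStats <- data.frame(protocol = rownames(groupStats), groupStats,
                           row.names = NULL)
  posthoc <- NULL
  if (!is.na(p) && p < alpha) {
    prs <- utils::combn(as.character(sort(unique(g))), 2)
    wide <- stats::reshape(
      results[c("subject", "protocol", metric)],
      direction = "wide", idvar = "subject", timevar = "protocol")
    posthoc <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      a <- prs[1, j]; b <- prs[2, j]
      xa <- wide[[paste(metric, a, sep = ".")]]
      xb <- wide[[paste(metric, b, sep = ".")]]
      pv <- pairedTP(xa, xb)
      data.frame(group1 = a, group2 = b, mean_diff = mean(xa - xb),
                 p = pv, significant = pv < alpha)
    }))
  }
  new("ComparisonReport", metric = metric, anovaF = Fv, anovaP = p,
      anovaDf = as.numeric(tab[["Df"]]), groupStats = groupStats,
      posthoc = posthoc, alpha = alpha)
}
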