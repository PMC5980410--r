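#' Summarise a change variable by height class
#'
#' Bins values into half-open height classes `[k*w, (k+1)*w)` keyed by the
#' first-epoch tree height and reports, per class, the median, the 10th and
#' 90th percentiles (linear-interpolation quantiles, type 7) and the notch
#' half-width `1.57 * IQR / sqrt(n)` — the standard boxplot approximation to
#' a 95% confidence interval on the median. Classes with fewer than `minN`
#' members are suppressed.
#'
#' @param heights first-epoch tree heights, metres.
#' @param values the change variable (height or radius delta), metres.
#' @param binWidth class width, metres.
#' @param minN minimum class size; smaller classes are dropped.
#' @return data.frame: `binLower`, `binUpper`, `n`, `median`, `p10`, `p90`,
#'   `iqr`, `notchHalfwidth`.
#' @examples
#' binByHeight(runif(200, 0, 40), rnorm(200, 0.5, 0.2), binWidth = 10,
#'             minN = 10)
#' @export
binByHeight <- function(heights, values, binWidth = 5, minN = 20L) {
  stopifnot(length(heights) == length(values))
  ok <- is.finite(heights) & is.finite(values)
  heights <- heights[ok]; values <- values[ok]
  if (!length(heights)) stop("no finite observations to bin", call. = FALSE)
  bin <- floor(heights / binWidth)
  out <- lapply(sort(unique(bin)), function(b) {
    v <- values[bin == b]
    if (length(v) < minN) return(NULL)
    q <- quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7, names = FALSE)
    data.frame(binLower = b * binWidth, binUpper = (b + 1) * binWidth,
               n = length(v), median = q[3], p10 = q[1], p90 = q[5],
               iqr = q[4] - q[2],
               notchHalfwidth = 1.57 * (q[4] - q[2]) / sqrt(length(v)))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(binLower = numeric(), binUpper = numeric(),
                      n = integer(), median = numeric(), p10 = numeric(),
                      p90 = numeric(), iqr = numeric(),
                      notchHalfwidth = numeric())
  }
  out
}

# shared implementation for the two by-size summaries
.change_by_size <- function(matches, column, binWidth, minN) {
  s <- binByHeight(matches$height_1, matches[[column]], binWidth = binWidth,
                   minN = minN)
  rho <- NA_real_; p <- NA_real_
  if (nrow(s) >= 3L) {
    ct <- suppressWarnings(
      cor.test((s$binLower + s$binUpper) / 2, s$median, method = "spearman")
    )
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  list(summary = s, spearmanRho = rho, spearmanP = p)
}

#' Height growth distribution by size class
#'
#' Summarises matched, filtered height changes (`d_height`) against the
#' first-epoch height class and reports a monotonicity statistic: the
#' Spearman correlation between class midpoint and class median.
#'
#' @param matches filtered match table ([applyGrowthFilters()]).
#' @param binWidth class width, metres.
#' @param minN minimum class size.
#' @return list: `summary` ([binByHeight()] table), `spearmanRho`,
#'   `spearmanP`.
#' @export
growthBySize <- function(matches, binWidth = 5, minN = 20L) {
  .change_by_size(matches, "d_height", binWidth, minN)
}

#' Crown-radius change distribution by size class
#'
#' @rdname growthBySize
#' @export
radiusChangeBySize <- function(matches, binWidth = 5, minN = 20L) {
  .change_by_size(matches, "d_radius", binWidth, minN)
}
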