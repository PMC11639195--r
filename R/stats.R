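#' @include accessors.R
NULL

group_frame <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  if (length(groups) < 2L || any(vapply(groups, length, 1L) < 2L))
    stop("need >= 2 groups with >= 2 values each")
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups)))
}

#' One-way analysis of variance across filters
#'
#' Classical one-way F statistic for equality of group means (e.g. percent
#' PSNR increases of the five filters across images), with the p-value from
#' the F distribution. In the fully degenerate case (zero between-group and
#' zero within-group variance) the exact limit F = 0, p = 1 is reported; a
#' zero within-group variance with distinct means gives F = Inf, p = 0.
#'
#' @param groups named list of numeric vectors (one per filter), each with
#'   at least two values.
#' @return list with elements `F`, `p`, `dfBetween`, `dfWithin`.
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4)))  # F = 1.5
#' @export
oneWayAnova <- function(groups) {
  df <- group_frame(groups)
  k <- nlevels(df$group); n <- nrow(df)
  eps <- 1e-12 * max(1, mean(df$value)^2)
  ssw <- sum(tapply(df$value, df$group, function(v) sum((v - mean(v))^2)))
  ssb <- sum(tapply(df$value, df$group, length) *
             (tapply(df$value, df$group, mean) - mean(df$value))^2)
  if (ssb == 0)
    return(list(F = 0, p = 1, dfBetween = k - 1L, dfWithin = n - k))
  if (ssw <= eps)
    return(list(F = Inf, p = 0, dfBetween = k - 1L, dfWithin = n - k))
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       dfBetween = tab[["Df"]][1], dfWithin = tab[["Df"]][2])
}

#' Tukey honestly-significant-difference pairwise comparison
#'
#' Pairwise group mean differences with studentized-range confidence
#' intervals and family-wise adjusted p-values; a pair is flagged
#' significant when its adjusted p falls below `1 - confLevel`.
#'
#' @param groups named list of numeric vectors, as in [oneWayAnova()].
#' @param confLevel family-wise confidence level (default 0.95).
#' @return data.frame with columns `pair`, `diff`, `lwr`, `upr`, `pAdj`,
#'   `significant`.
#' @export
tukeyHsd <- function(groups, confLevel = 0.95) {
  df <- group_frame(groups)
  means <- tapply(df$value, df$group, mean)
  ssw <- sum(tapply(df$value, df$group, function(v) sum((v - mean(v))^2)))
  if (ssw <= 1e-12 * max(1, mean(df$value)^2)) {
    lev <- levels(df$group)
    pairs <- t(combn(lev, 2))
    d <- means[pairs[, 2]] - means[pairs[, 1]]
    return(data.frame(pair = paste(pairs[, 2], pairs[, 1], sep = "-"),
                      diff = as.numeric(d), lwr = as.numeric(d),
                      upr = as.numeric(d),
                      pAdj = ifelse(abs(d) > 0, 0, 1),
                      significant = abs(d) > 0, row.names = NULL))
  }
  fit <- aov(value ~ group, data = df)
  tk <- TukeyHSD(fit, conf.level = confLevel)$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], pAdj = tk[, "p adj"],
             significant = tk[, "p adj"] < 1 - confLevel,
             row.names = NULL)
}
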