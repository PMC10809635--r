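# Brute-force one-way ANOVA + Tukey-Kramer oracle, computed from first
# principles (explicit sums of squares, ptukey/qtukey), independent of
# stats::aov / stats::TukeyHSD.
oracle_oneway <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  n <- tapply(x, g, length)
  m <- tapply(x, g, mean)
  grand <- mean(x)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((x - m[g])^2)
  df1 <- k - 1
  df2 <- length(x) - k
  msw <- ssw / df2
  f <- (ssb / df1) / msw
  pairs <- utils::combn(levels(g), 2)
  tuk <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    diff <- m[[j]] - m[[i]]
    se <- sqrt(msw * (1 / n[[i]] + 1 / n[[j]]))
    q <- abs(diff) / (se / sqrt(2))
    half <- stats::qtukey(0.95, k, df2) / sqrt(2) * se
    c(diff = diff, lwr = diff - half, upr = diff + half,
      p = stats::ptukey(q, k, df2, lower.tail = FALSE))
  })
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       ssb = ssb, ssw = ssw, df1 = df1, df2 = df2,
    tukey = tibble::tibble(contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
                           estimate = tuk["diff", ], conf.low = tuk["lwr", ],
                           conf.high = tuk["upr", ], adj.p.value = tuk["p", ]))
}
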