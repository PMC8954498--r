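# Independent scalar oracles for the disproportionality formulas, written
# directly as plain arithmetic (no shared code with the package internals).

z95 <- qnorm(0.975)

oracle_prr <- function(a, b, c, d) {
  p <- (a / (a + c)) / (b / (b + d))
  se <- sqrt(1 / a - 1 / (a + c) + 1 / b - 1 / (b + d))
  list(point = p, lo = exp(log(p) - z95 * se), hi = exp(log(p) + z95 * se))
}

oracle_ror <- function(a, b, c, d) {
  p <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(point = p, lo = exp(log(p) - z95 * se), hi = exp(log(p) + z95 * se))
}

oracle_ic <- function(a, b, c, d) {
  n <- a + b + c + d
  ae <- (a + b) * (a + c) / n
  point <- log2((a + 0.5) / (ae + 0.5))
  list(a_exp = ae,
       ic = point,
       ic025 = point - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5),
       ic975 = point + 2.4 * (a + 0.5)^(-0.5) - 0.5 * (a + 0.5)^(-1.5))
}

# odds ratio and Wald interval through logistic regression: an
# algorithmically independent route to the same estimand
oracle_ror_glm <- function(a, b, c, d) {
  fit <- suppressWarnings(glm(
    cbind(ev, no) ~ x, family = binomial,
    data = data.frame(x = c(1, 0), ev = c(a, b), no = c(c, d)),
    control = glm.control(epsilon = 1e-14, maxit = 200)))
  beta <- coef(fit)[["x"]]
  se <- sqrt(vcov(fit)["x", "x"])
  c(point = exp(beta), lo = exp(beta - z95 * se), hi = exp(beta + z95 * se))
}

oracle_chi2 <- function(a, b, c, d) {
  unname(suppressWarnings(
    stats::chisq.test(matrix(c(a, c, b, d), 2), correct = TRUE))$statistic)
}

random_cells <- function(n, seed, min_count = 1) {
  withr::with_seed(seed, data.frame(
    a = sample(min_count:200, n, replace = TRUE),
    b = sample(min_count:300, n, replace = TRUE),
    c = sample(min_count:300, n, replace = TRUE),
    d = sample(min_count:2000, n, replace = TRUE)
  ))
}
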