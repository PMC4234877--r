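# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no data files are stored.

# Inflated-beta responses on given covariates: the zoib generating process.
make_zoib_data <- function(n, beta = c(1.0, 0.02), delta = 1.2,
                           p0 = 0.03, p1 = 0.12, seed = 1,
                           x_range = c(0, 100)) {
  set.seed(seed)
  x <- stats::runif(n, x_range[1], x_range[2])
  X <- cbind(1, x)
  mu <- stats::plogis(drop(X %*% beta))
  phi <- exp(delta)
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  u <- stats::runif(n)
  y[u < p0] <- 0
  y[u >= p0 & u < p0 + p1] <- 1
  data.frame(x = x, y = y)
}

# Tiny trial file on disk (3 rows with known states), returns the path.
write_state_fixture <- function(path = tempfile(fileext = ".csv")) {
  d <- data.frame(subject_id = c("S1", "S1", "S2"),
                  visit = c(1, 2, 1),
                  eq5d_state = c("11111", "21222", "11321"))
  for (v in eq5dmap::qlq_domains) d[[v]] <- c(90, 70, 50)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
exkurtosis <- function(x) mean((x - mean(x))^4) / stats::sd(x)^4 - 3
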