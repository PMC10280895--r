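# Shared fixtures: small deterministic traces and schedules built in code.

# the reference 12 s / 54 s schedule with uniform toss spacing
ref_schedule <- function() build_schedule(12, 54, jitter_fraction = 0)

# fully visible constant-intensity trace on a regular grid over [0, 66)
constant_trace <- function(level = 2, dt = 0.1, total = 66,
                           visible = TRUE, child = "c1", coder = "k1") {
  t <- seq(0, total - 1e-9, by = dt)
  n <- length(t)
  emotion_trace(child, coder, t,
                sadness = rep(level, n), anger = rep(level, n),
                contempt = rep(level, n),
                visible = rep(visible, n))
}

# random piecewise-linear trace with a given visible fraction; knots sit
# on a 1 ms grid so a 1 ms-step oracle sees no straddled segments
random_trace <- function(n = 200, total = 66, p_visible = 0.4) {
  t <- sort(sample(seq(0.001, total - 0.001, by = 0.001), n))
  emotion_trace("c1", "k1", t,
                sadness = stats::runif(n, 0, 5),
                anger = stats::runif(n, 0, 5),
                contempt = stats::runif(n, 0, 5),
                visible = stats::runif(n) < p_visible)
}

# dense Riemann-sum oracle for the visibility-masked normalized AUC:
# midpoint evaluation of the piecewise-linear curve and the left-sample
# visibility flag on a 1 ms grid
riemann_auc_oracle <- function(trace, channel, window, dt = 0.001) {
  tg <- seq(window[1] + dt / 2, window[2], by = dt)
  idx <- findInterval(tg, trace$time_s)
  n <- length(trace$time_s)
  val <- numeric(length(tg))
  vis <- logical(length(tg))
  inside <- idx >= 1
  i <- pmin(idx[inside], n)
  i2 <- pmin(i + 1L, n)
  t0 <- trace$time_s[i]; t1 <- trace$time_s[i2]
  v0 <- trace[[channel]][i]; v1 <- trace[[channel]][i2]
  w <- ifelse(t1 > t0, (tg[inside] - t0) / (t1 - t0), 0)
  w <- pmin(pmax(w, 0), 1)
  val[inside] <- v0 + w * (v1 - v0)
  vis[inside] <- trace$visible[i]
  area <- sum(val[vis]) * dt
  vis_s <- sum(vis) * dt
  10 * area / vis_s
}

# small config tweak helper
with_config <- function(config, ...) {
  mods <- list(...)
  for (nm in names(mods)) {
    parts <- strsplit(nm, "\\.")[[1]]
    expr <- paste0("config", paste0("[['", parts, "']]", collapse = ""))
    eval(parse(text = paste0(expr, " <- mods[[nm]]")))
  }
  config
}
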