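#' growthctrl: coarse-grained kinetic submodels of bacterial growth rate control
#'
#' Kinetic submodels of growth rate control in *E. coli* — amino-acid
#' biosynthesis and transport, tRNA charging, RelA/SpoT ppGpp kinetics,
#' ppGpp-dependent transcription, transcriptional attenuation and network
#' component analysis — plus a reduced host cell that couples them for
#' nutrient-shift and ppGpp-clamp experiments.
#'
#' @keywords internal
"_PACKAGE"

# --- small validation helpers ------------------------------------------------

stop_domain <- function(...) stop(..., call. = FALSE)

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop_domain(what, " must be finite and >= 0")
  invisible(x)
}

check_pos <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop_domain(what, " must be finite and > 0")
  invisible(x)
}

# Align a named vector onto the amino-acid (or species) index of a network;
# unknown names are an identifier error, missing names are an error too.
align_ids <- function(x, ids, what) {
  if (is.null(names(x))) {
    if (length(x) != length(ids))
      stop_domain(what, ": expected ", length(ids), " values or a named vector")
    names(x) <- ids
    return(x)
  }
  unknown <- setdiff(names(x), ids)
  if (length(unknown) > 0)
    stop_domain(what, ": unknown identifier(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(ids, names(x))
  if (length(missing) > 0)
    stop_domain(what, ": missing identifier(s): ", paste(missing, collapse = ", "))
  x[ids]
}

# Saturation factor AA/(AA + K), defined algebraically so AA = 0 gives 0
# without division exceptions (K > 0).
sat <- function(conc, K) {
  ifelse(conc <= 0, 0, conc / (conc + K))
}

# Inhibition factor 1/(1 + AA/K); K may be Inf (inhibition removed) -> 1.
inhib <- function(conc, K) {
  ifelse(is.infinite(K), 1, 1 / (1 + conc / K))
}

# --- adaptive implicit (backward Euler + Newton) -----------------------------

# Stiff-capable integrator: adaptive backward Euler with chord-Newton
# iterations (numerical Jacobian, refreshed per step) and Richardson
# extrapolation for error control (one full step vs two half steps; the
# extrapolated second-order value is returned).  The charging relaxation is
# stiff — synthetase capacity exceeds translation demand by orders of
# magnitude, so uncharged pools equilibrate on sub-millisecond scales — and
# an explicit method would be stability-limited there.
ode_bdf1 <- function(f, y0, t0, t1, rtol = 1e-8, atol = 1e-10,
                     max_steps = 5e4, nonneg = FALSE, n_quad = 0) {
  n <- length(y0)
  na <- n - n_quad           # active states; trailing n_quad are quadrature
  act <- seq_len(na)
  eye <- diag(na)
  newton_tol <- max(1e-11, 1e-3 * rtol)
  jacobian <- function(t, y) {
    f0 <- f(t, y)
    J <- matrix(0, na, na)
    for (j in act) {
      dy <- max(1e-8, 1e-8 * abs(y[j]))
      yp <- y; yp[j] <- yp[j] + dy
      J[, j] <- (f(t, yp) - f0)[act] / dy
    }
    J
  }
  # chord Newton with a Jacobian shared across the full- and half-step
  # solves of one attempt (rebuilt only when the step is retried)
  be_step <- function(t, y, h, J) {
    ft <- t + h
    yg <- y + h * f(t, y)  # explicit predictor
    M <- eye - h * J
    yk <- yg
    ok <- FALSE
    for (it in 1:8) {
      fk <- f(ft, yk)
      g <- yk[act] - y[act] - h * fk[act]
      step <- tryCatch(solve(M, g), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      yk[act] <- yk[act] - step
      if (max(abs(step) / pmax(abs(yk[act]), atol)) < newton_tol) {
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
    if (n_quad > 0) {
      qi <- (na + 1):n
      yk[qi] <- y[qi] + h * f(ft, yk)[qi]
    }
    if (any(!is.finite(yk))) return(NULL)
    yk
  }
  y <- as.numeric(y0)
  t <- t0
  h <- t1 - t0  # optimistic start: near a fixed point one step suffices
  steps <- 0L
  while (t < t1 - 1e-12 * (t1 - t0)) {
    if (steps >= max_steps)
      stop_domain("ode_bdf1: step limit reached at t = ", signif(t, 6))
    h <- min(h, t1 - t)
    J <- jacobian(t, y)
    y1 <- be_step(t, y, h, J)
    ya <- be_step(t, y, h / 2, J)
    yb <- if (!is.null(ya)) be_step(t + h / 2, ya, h / 2, J) else NULL
    if (is.null(y1) || is.null(yb)) {
      h <- h / 4
      steps <- steps + 1L
      next
    }
    # error controlled on the active states only: quadrature states are
    # integrals of rates that are accurate once the active states are
    sc <- atol + rtol * pmax(abs(y[act]), abs(yb[act]))
    err <- sqrt(mean(((yb[act] - y1[act]) / sc)^2))
    if (!is.finite(err)) {
      h <- h / 4
      steps <- steps + 1L
      next
    }
    if (err <= 1) {
      t <- t + h
      y <- 2 * yb - y1  # Richardson extrapolation (2nd order)
      if (nonneg) y[y < 0] <- 0
    }
    fac <- if (err > 0) 0.9 * err^(-0.5) else 6
    h <- h * min(6, max(0.05, fac))
    steps <- steps + 1L
  }
  y
}

# --- adaptive Cash-Karp RK45 -------------------------------------------------

# Minimal adaptive embedded Runge-Kutta (Cash-Karp 4(5)) integrator.  The
# systems integrated here (tRNA charging relaxation over ~1 s windows, ppGpp
# decay/steady-state runs) are low-dimensional and only mildly stiff, so an
# explicit adaptive method with tight tolerances is adequate and keeps the
# package dependency-free.  States can optionally be floored at zero after
# each accepted step (pool clipping).
ode_rk45 <- function(f, y0, t0, t1, rtol = 1e-8, atol = 1e-10,
                     max_steps = 2e5, nonneg = FALSE) {
  # Cash-Karp tableau
  a <- list(c(),
            c(1 / 5),
            c(3 / 40, 9 / 40),
            c(3 / 10, -9 / 10, 6 / 5),
            c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
            c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096))
  b5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  b4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)
  cs <- c(0, 1 / 5, 3 / 10, 3 / 5, 1, 7 / 8)

  y <- as.numeric(y0)
  t <- t0
  h <- (t1 - t0) / 100
  n <- length(y)
  k <- matrix(0, n, 6)
  steps <- 0L
  while (t < t1) {
    if (steps >= max_steps)
      stop_domain("ode_rk45: step limit reached at t = ", signif(t, 6),
                  " (state: ", paste(signif(y, 4), collapse = ", "), ")")
    h <- min(h, t1 - t)
    k[, 1] <- f(t, y)
    for (i in 2:6) {
      yi <- y + h * as.numeric(k[, seq_len(i - 1), drop = FALSE] %*% a[[i]])
      k[, i] <- f(t + cs[i] * h, yi)
    }
    y5 <- y + h * as.numeric(k %*% b5)
    y4 <- y + h * as.numeric(k %*% b4)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err)) {
      h <- h / 10
      steps <- steps + 1L
      next
    }
    if (err <= 1) {
      t <- t + h
      y <- y5
      if (nonneg) y[y < 0] <- 0
    }
    fac <- if (err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
    steps <- steps + 1L
  }
  y
}
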