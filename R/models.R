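# Markov gating schemes: sequential binding chains C0 ... Cm -> O and the
# two-state C-O scheme. Rate laws are stored per directed edge as
# multiplier * parameter * (concentration or 1); parameters are either free
# (elements of theta) or fixed gating rates.

new_kinetic_model <- function(label, n_states, binding_steps, cooperative,
                              open_states, edges, fixed_params, free_params,
                              state_names) {
  stopifnot(nrow(edges) > 0, all(edges$from != edges$to))
  structure(list(
    label = label,
    n_states = as.integer(n_states),
    binding_steps = as.integer(binding_steps),
    cooperative = isTRUE(cooperative),
    open_states = as.integer(open_states),
    edges = edges,
    fixed_params = fixed_params,
    free_params = free_params,
    state_names = state_names
  ), class = "kinetic_model")
}

#' Build a sequential ligand-binding and gating scheme
#'
#' Constructs a chain of closed states `C0 ... Cm` connected by `m` ligand
#' binding steps, followed by a single conformational opening step `Cm <-> O`
#' with fixed rates `e_plus` (opening, s^-1) and `e_minus` (closing, s^-1).
#' With `cooperative = TRUE` every binding step carries its own microscopic
#' association and dissociation rate (free parameters `k1, km1, ..., km<m>`,
#' 2m in total). With `cooperative = FALSE` the subunits are identical and
#' independent: the only free parameters are `kon` (M^-1 s^-1) and `koff`
#' (s^-1), and step j carries the statistical factors `(m - j + 1)` forward
#' and `j` backward that arise from aggregating site-occupancy microstates by
#' occupancy count.
#'
#' Models are labelled `<s>s<p>p` by their state count `s = m + 2` and free
#' parameter count `p`, so the cooperative family reads 3s2p, 4s4p, 5s6p,
#' 6s8p for m = 1..4.
#'
#' @param m number of binding steps (1 to 4).
#' @param cooperative logical; free per-step rates (TRUE) or shared
#'   microscopic rates with statistical factors (FALSE).
#' @param e_plus,e_minus fixed opening and closing rates in s^-1.
#' @return A `kinetic_model` object.
#' @examples
#' build_sequential_model(2, cooperative = TRUE, e_plus = 990, e_minus = 10)
#' @export
build_sequential_model <- function(m, cooperative = TRUE,
                                   e_plus = 990, e_minus = 10) {
  if (!is.numeric(m) || length(m) != 1 || !(m %in% 1:4))
    stop("unsupported model: number of binding steps must be 1, 2, 3 or 4")
  if (e_plus <= 0 || e_minus <= 0)
    stop("gating rates e_plus and e_minus must be strictly positive")
  s <- m + 2L
  state_names <- c(paste0("C", 0:m), "O")
  if (cooperative) {
    free <- as.vector(rbind(paste0("k", 1:m), paste0("km", 1:m)))
    edges <- data.frame(
      from = c(1:m, 2:(m + 1L)),
      to   = c(2:(m + 1L), 1:m),
      param = c(paste0("k", 1:m), paste0("km", 1:m)),
      multiplier = 1,
      conc_dep = rep(c(TRUE, FALSE), each = m),
      stringsAsFactors = FALSE
    )
  } else {
    free <- c("kon", "koff")
    edges <- data.frame(
      from = c(1:m, 2:(m + 1L)),
      to   = c(2:(m + 1L), 1:m),
      param = rep(c("kon", "koff"), each = m),
      multiplier = c(m:1, 1:m),
      conc_dep = rep(c(TRUE, FALSE), each = m),
      stringsAsFactors = FALSE
    )
  }
  gate <- data.frame(
    from = c(m + 1L, s), to = c(s, m + 1L),
    param = c("e_plus", "e_minus"), multiplier = 1,
    conc_dep = FALSE, stringsAsFactors = FALSE
  )
  new_kinetic_model(
    label = sprintf("%ds%dp", s, length(free)),
    n_states = s, binding_steps = m, cooperative = cooperative,
    open_states = s, edges = rbind(edges, gate),
    fixed_params = c(e_plus = e_plus, e_minus = e_minus),
    free_params = free, state_names = state_names
  )
}

#' Build the two-state C-O scheme with a ligand-dependent opening step
#'
#' The minimal gating scheme: a closed and an open state connected by a
#' single opening transition whose rate is proportional to the ligand
#' concentration. Both rates are free parameters.
#'
#' @param k_open_per_conc opening rate per unit concentration (M^-1 s^-1).
#' @param k_close closing rate (s^-1).
#' @return A `kinetic_model` with free parameters `k_open` and `k_close`;
#'   the supplied values are kept as the default parameter vector in
#'   `attr(, "theta_default")`.
#' @examples
#' build_co_model(1e6, 100)
#' @export
build_co_model <- function(k_open_per_conc, k_close) {
  if (!is.numeric(k_open_per_conc) || !is.numeric(k_close) ||
      k_open_per_conc <= 0 || k_close <= 0)
    stop("rates of the C-O model must be strictly positive")
  edges <- data.frame(
    from = c(1L, 2L), to = c(2L, 1L),
    param = c("k_open", "k_close"), multiplier = 1,
    conc_dep = c(TRUE, FALSE), stringsAsFactors = FALSE
  )
  mod <- new_kinetic_model(
    label = "C-O", n_states = 2L, binding_steps = 0L, cooperative = FALSE,
    open_states = 2L, edges = edges, fixed_params = numeric(0),
    free_params = c("k_open", "k_close"), state_names = c("C", "O")
  )
  attr(mod, "theta_default") <- c(k_open = k_open_per_conc, k_close = k_close)
  mod
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("Kinetic model %s: %d states (%s), %d binding step(s), %s\n",
              x$label, x$n_states, paste(x$state_names, collapse = " "),
              x$binding_steps,
              if (x$cooperative) "cooperative binding" else
                if (x$binding_steps > 0) "independent binding" else "C-O gating"))
  cat("  free parameters:", paste(x$free_params, collapse = ", "), "\n")
  if (length(x$fixed_params))
    cat("  fixed rates:",
        paste(sprintf("%s = %g /s", names(x$fixed_params), x$fixed_params),
              collapse = ", "), "\n")
  invisible(x)
}

check_theta <- function(model, theta) {
  k <- length(model$free_params)
  if (length(theta) != k)
    stop(sprintf("theta must have length %d (%s)", k,
                 paste(model$free_params, collapse = ", ")))
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("all rate parameters must be finite and strictly positive")
  setNames(as.numeric(theta), model$free_params)
}

# Edge coefficients (multiplier * parameter value) for a given theta; the
# concentration factor is applied separately.
edge_coefficients <- function(model, theta) {
  theta <- check_theta(model, theta)
  vals <- c(theta, model$fixed_params)
  model$edges$multiplier * vals[model$edges$param]
}

#' Q-matrix of a kinetic model at one concentration
#'
#' Assembles the infinitesimal generator of the gating Markov chain for a
#' parameter vector `theta` at ligand concentration `conc`: off-diagonal
#' entries are the transition rates (ligand-dependent edges scaled linearly
#' by `conc`), the diagonal makes every row sum to zero.
#'
#' @param model a `kinetic_model`.
#' @param theta positive parameter vector, one entry per free parameter.
#' @param conc ligand concentration in molar (>= 0).
#' @return A square rate matrix in s^-1 with state names as dimnames.
#' @examples
#' m <- build_co_model(1e6, 100)
#' q_matrix(m, c(1e6, 100), conc = 1e-4)
#' @export
q_matrix <- function(model, theta, conc) {
  if (!is.numeric(conc) || length(conc) != 1 || conc < 0)
    stop("conc must be a single non-negative concentration in molar")
  coef <- edge_coefficients(model, theta)
  s <- model$n_states
  Q <- matrix(0, s, s, dimnames = list(model$state_names, model$state_names))
  rate <- coef * ifelse(model$edges$conc_dep, conc, 1)
  for (i in seq_len(nrow(model$edges)))
    Q[model$edges$from[i], model$edges$to[i]] <-
      Q[model$edges$from[i], model$edges$to[i]] + rate[i]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

# exp(M) for a rate-matrix argument: eigendecomposition with a condition
# guard, falling back to scaling-and-squaring when the eigenvector basis is
# ill-conditioned (near-defective Q at extreme parameters).
expm_rate <- function(M, kappa_max = 1e12) {
  e <- tryCatch(eigen(M), error = function(err) NULL)
  if (!is.null(e) && all(is.finite(abs(e$vectors)))) {
    kap <- tryCatch(kappa(e$vectors, exact = FALSE), error = function(err) Inf)
    if (is.finite(kap) && kap < kappa_max) {
      P <- e$vectors %*% (exp(e$values) * solve(e$vectors))
      if (is.complex(P)) {
        if (max(abs(Im(P))) < 1e-9) P <- Re(P) else P <- NULL
      }
      if (!is.null(P)) return(P)
    }
  }
  as.matrix(Matrix::expm(M))
}

#' Propagate a state distribution over one constant-concentration interval
#'
#' Computes `p0 %*% exp(Q(conc, theta) * dt)`, the exact solution of the
#' master equation dp/dt = p Q on an interval of constant concentration. The
#' matrix exponential is evaluated by eigendecomposition, with a
#' scaling-and-squaring fallback when the eigenvector matrix is
#' ill-conditioned.
#'
#' @param model a `kinetic_model`.
#' @param theta positive parameter vector.
#' @param p0 state distribution at the start of the interval (sums to 1).
#' @param conc ligand concentration in molar, constant over the interval.
#' @param dt interval length in seconds (> 0).
#' @return The state distribution after `dt` seconds.
#' @export
propagate <- function(model, theta, p0, conc, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  p0 <- check_distribution(model, p0)
  Q <- q_matrix(model, theta, conc)
  p <- as.numeric(p0 %*% expm_rate(Q * dt))
  if (any(!is.finite(p)))
    stop(sprintf(
      "numerical propagation failure on segment at conc = %g M, dt = %g s",
      conc, dt))
  if (abs(sum(p) - 1) > 1e-10)
    stop("probability mass not conserved during propagation")
  p[p < 0 & p > -1e-12] <- 0
  setNames(p / sum(p), model$state_names)
}

check_distribution <- function(model, p) {
  if (length(p) != model$n_states)
    stop(sprintf("state distribution must have length %d", model$n_states))
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    stop("state distribution entries must be >= 0 and sum to 1")
  as.numeric(p)
}

#' Stationary state distribution at a fixed concentration
#'
#' Solves `p Q = 0`, `sum(p) = 1` by least squares. For sequential chains at
#' `conc > 0` this equals the detailed-balance product of equilibrium
#' constants. At `conc = 0` a chain with ligand-dependent forward rates is
#' reducible and all mass collects in `C0`; the returned distribution is then
#' flagged with `attr(, "degenerate") = TRUE`.
#'
#' @inheritParams q_matrix
#' @return Named probability vector with a `degenerate` attribute.
#' @export
stationary_distribution <- function(model, theta, conc) {
  Q <- q_matrix(model, theta, conc)
  s <- model$n_states
  A <- rbind(t(Q), rep(1, s))
  p <- tryCatch(qr.solve(A, c(rep(0, s), 1)), error = function(e) {
    # numerically rank-deficient at extreme rates: take the null vector of
    # Q^T from its SVD instead
    sv <- svd(t(Q))
    v <- sv$v[, s]
    if (sum(v) < 0) v <- -v
    v
  })
  p <- pmax(p, 0)
  if (sum(p) == 0) stop("failed to compute a stationary distribution")
  p <- p / sum(p)
  degen <- conc == 0 && any(model$edges$conc_dep)
  structure(setNames(p, model$state_names), degenerate = degen)
}

#' Open probability of a state distribution
#'
#' Sum of the probabilities of the conducting states of the model.
#'
#' @param p state distribution.
#' @param model a `kinetic_model`.
#' @return A number in `[0, 1]`.
#' @export
open_probability <- function(p, model) {
  p <- check_distribution(model, p)
  min(max(sum(p[model$open_states]), 0), 1)
}
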