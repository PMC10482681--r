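#' Hidden Markov model parameters for categorical behaviour sequences
#'
#' @param pi Initial-state probability vector (length K).
#' @param A K x K transition matrix; `A[i, j]` is P(state j at t+1 | state i
#'   at t). Rows must sum to 1.
#' @param B K x V emission matrix; `B[i, v]` is P(behaviour v | state i).
#'   Rows must sum to 1.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(pi, A, B) {
  pi <- as.numeric(pi); A <- as.matrix(A); B <- as.matrix(B)
  K <- length(pi)
  if (!all(dim(A) == c(K, K))) stop("A must be K x K")
  if (nrow(B) != K) stop("B must have K rows")
  if (any(pi < 0) || any(A < 0) || any(B < 0))
    stop("probabilities must be non-negative")
  chk <- function(x, what) {
    if (any(abs(x - 1) > 1e-9))
      stop(what, " must sum to 1 (tolerance 1e-9)")
  }
  chk(sum(pi), "pi")
  chk(rowSums(A), "each row of A")
  chk(rowSums(B), "each row of B")
  structure(list(pi = pi, A = A, B = B, K = K, V = ncol(B)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, digits = 3, ...) {
  cat(sprintf("Categorical HMM: K = %d states, V = %d symbols\n", x$K, x$V))
  cat("Transition matrix A:\n")
  print(round(x$A, digits))
  invisible(x)
}

#' Initialise HMM parameters
#'
#' The initial transition matrix assumes equal probabilities for all
#' transitions (no a priori information), `pi` is uniform, and the emission
#' matrix starts from a template guess of the probability of each behaviour
#' in each state — by default [default_emission_template()] when `K = 3`
#' and the vocabulary is the default 15-action set, otherwise uniform.
#'
#' @param K Number of hidden states (default 3).
#' @param vocab A [behavior_vocabulary()] fixing V and symbol order.
#' @param emission_template Optional K x V matrix of starting emission
#'   probabilities; rows must sum to 1.
#' @param jitter Non-negative scalar; if positive, each template entry is
#'   multiplied by `exp(jitter * z)` with standard-normal `z`, then rows are
#'   renormalised. Useful for multi-start fitting.
#' @param seed Integer seed making the jitter deterministic.
#' @return An `hmm_params` object.
#' @export
init_params <- function(K = 3, vocab = behavior_vocabulary(),
                        emission_template = NULL, jitter = 0, seed = 1L) {
  V <- length(vocab$actions)
  if (K < 1) stop("K must be >= 1")
  if (is.null(emission_template)) {
    emission_template <- if (K == 3 && V == 15)
      default_emission_template(vocab)
    else matrix(1 / V, K, V)
  }
  B <- as.matrix(emission_template)
  if (!all(dim(B) == c(K, V))) stop("emission template must be K x V")
  rs <- rowSums(B)
  if (any(rs <= 0)) stop("emission template has a zero row-sum")
  B <- B / rs
  if (jitter > 0) {
    z <- with_local_seed(seed, matrix(stats::rnorm(K * V), K, V))
    B <- B * exp(jitter * z)
    B <- B / rowSums(B)
  }
  A <- matrix(1 / K, K, K)
  hmm_params(rep(1 / K, K), A, B)
}

#' Default 3-state emission template
#'
#' Starting guess for the probability of each behaviour in each state:
#' the energy-conservation state concentrates mass on sitting and
#' shivering; the exploration-with-feeding state on eating, moving out,
#' moving back and drinking; the exploration-without-feeding state on
#' locomotor and maintenance actions (walking, digging, bedding retrieval,
#' pushing bedding, standing up, the grooming actions and turning); all
#' other entries get a 0.01 floor before row renormalisation.
#'
#' @param vocab A [behavior_vocabulary()] containing the default actions.
#' @return A 3 x V row-stochastic matrix.
#' @export
default_emission_template <- function(vocab = behavior_vocabulary()) {
  V <- length(vocab$actions)
  B <- matrix(0.01, 3, V, dimnames = list(NULL, vocab$actions))
  focal <- list(
    c("sitting", "shivering"),
    c("eating", "moving out", "moving back", "drinking"),
    c("walking", "digging", "bedding retrieval", "pushing bedding",
      "standing up", "head grooming", "lower body grooming",
      "grooming tail", "turning"))
  for (k in 1:3) {
    f <- intersect(focal[[k]], vocab$actions)
    if (length(f) == 0) stop("vocabulary lacks the template's focal actions")
    B[k, f] <- (1 - 0.01 * (V - length(f))) / length(f)
  }
  B / rowSums(B)
}

#' Forward log-likelihood of an observation sequence
#'
#' Computes log P(obs | params) with the scaled forward recursion
#' (numerically safe for the 10,800-step sequences of 180-min recordings).
#' Returns `-Inf`, not an error, when some step has zero probability under
#' every state.
#'
#' @param params An [hmm_params()].
#' @param obs An `observation_sequence` from [encode_observations()], or a
#'   0-based integer vector.
#' @return Log-likelihood scalar.
#' @export
forward_log_likelihood <- function(params, obs) {
  obs <- obs_codes(obs, params$V)
  cpp_forward_loglik(params$pi, params$A, params$B, obs)
}

#' Fit a categorical HMM by multi-sequence Baum-Welch
#'
#' Expectation-maximisation over one or more observation sequences pooled
#' into a single model: expected transition and emission counts are summed
#' across sequences (each sequence restarts from `pi`) before the M-step.
#' Iteration stops when the relative log-likelihood improvement falls below
#' `tol` or `max_iter` is reached. After each M-step, emission entries
#' below `1e-8` are floored and rows renormalised so unseen behaviours do
#' not freeze at exact zero; `pi` is re-estimated as the average
#' first-step posterior across sequences.
#'
#' @param params0 Starting [hmm_params()], e.g. from [init_params()].
#' @param obs_list A single observation sequence or a list of them; each of
#'   length >= 2.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @return An object of class `hmm_fit`: list with `params`,
#'   `loglik_trace`, `n_iter` and `converged`.
#' @export
baum_welch_fit <- function(params0, obs_list, tol = 1e-6, max_iter = 500) {
  if (!inherits(params0, "hmm_params")) stop("params0 must be hmm_params")
  if (inherits(obs_list, "observation_sequence") || !is.list(obs_list))
    obs_list <- list(obs_list)
  if (length(obs_list) == 0) stop("need at least one sequence")
  obs_list <- lapply(obs_list, obs_codes, V = params0$V)
  if (any(vapply(obs_list, length, 1L) < 2))
    stop("each sequence must have length >= 2")
  K <- params0$K; V <- params0$V
  pi <- params0$pi; A <- params0$A; B <- floor_renorm(params0$B, 1e-8)
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  ll_prev <- NA_real_
  for (it in seq_len(max_iter)) {
    trans_num <- matrix(0, K, K)
    emis_num <- matrix(0, K, V)
    gamma1 <- numeric(K)
    gamma_sum <- numeric(K)
    last_gamma <- numeric(K)
    ll <- 0
    for (obs in obs_list) {
      fb <- cpp_forward_backward(pi, A, B, obs)
      ll <- ll + fb$loglik
      trans_num <- trans_num + fb$xi_sum
      emis_num <- emis_num + fb$emis_num
      gamma1 <- gamma1 + fb$gamma1
      gamma_sum <- gamma_sum + colSums(fb$gamma)
    }
    n_iter <- it
    trace <- c(trace, ll)
    # M-step
    pi <- gamma1 / length(obs_list)
    denomA <- rowSums(trans_num)
    A <- trans_num / pmax(denomA, .Machine$double.xmin)
    A[denomA <= 0, ] <- 1 / K   # state never occupied before t = T
    A <- A / rowSums(A)
    B <- floor_renorm(emis_num / pmax(gamma_sum, .Machine$double.xmin), 1e-8)
    if (!is.na(ll_prev) && (ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  structure(list(params = hmm_params(pi, A, B), loglik_trace = trace,
                 n_iter = n_iter, converged = converged),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("Baum-Welch fit: %d iterations, %s (final loglik %.2f)\n",
              x$n_iter, if (x$converged) "converged" else "not converged",
              utils::tail(x$loglik_trace, 1)))
  print(x$params)
  invisible(x)
}

#' Viterbi decoding of the most probable state path
#'
#' Ties at each backtrack step are broken toward the lowest state index so
#' decoding is deterministic. The returned sequence carries raw 0-based
#' state indices; use [assign_semantic_labels()] and [relabel()] to map
#' them to semantic states 1/2/3.
#'
#' @param params An [hmm_params()].
#' @param obs Observation sequence (0-based codes).
#' @param animal_id,bin_s,t0 Metadata attached to the result.
#' @return A `state_sequence` (raw) with attribute `logprob`, the log joint
#'   probability of the returned path.
#' @export
viterbi_decode <- function(params, obs, animal_id = NULL, bin_s = 1,
                           t0 = 0) {
  codes <- obs_codes(obs, params$V)
  if (is.null(animal_id))
    animal_id <- if (inherits(obs, "observation_sequence"))
      obs$animal_id else "animal"
  res <- cpp_viterbi(log(params$pi), log(params$A), log(params$B), codes)
  if (!is.finite(res$logprob)) {
    bad <- first_impossible_step(params, codes)
    stop(sprintf("no state path has positive probability; first impossible step at t = %d (symbol code %d)",
                 bad, codes[bad]))
  }
  out <- state_sequence(res$path, semantic = FALSE, animal_id = animal_id,
                        bin_s = bin_s, t0 = t0)
  attr(out, "logprob") <- res$logprob
  out
}

#' Map fitted states to the semantic state labels 1/2/3
#'
#' Resolves label switching for the three-state behavioural model: the
#' fitted state with the highest eating emission becomes semantic state 2
#' (exploration with feeding); of the remaining two, the one with the
#' larger combined sitting + shivering emission becomes state 1 (energy
#' conservation); the remainder is state 3 (exploration without feeding).
#' Ties go to the lower raw index.
#'
#' @param params A fitted [hmm_params()] with K = 3.
#' @param vocab Vocabulary containing "eating", "sitting" and "shivering".
#' @return A `state_label_map`: integer vector `map` such that `map[r + 1]`
#'   is the semantic state of raw state `r`.
#' @export
assign_semantic_labels <- function(params, vocab = behavior_vocabulary()) {
  if (params$K != 3)
    stop("semantic labelling is defined only for the 3-state model")
  need <- c("eating", "sitting")
  if (!all(need %in% vocab$actions))
    stop("vocabulary must contain 'eating' and 'sitting'")
  eat <- params$B[, vocab$index[["eating"]] + 1L]
  s2 <- which.max(eat)                       # which.max takes the lowest index on ties
  rest <- setdiff(1:3, s2)
  sit <- params$B[rest, vocab$index[["sitting"]] + 1L]
  if ("shivering" %in% vocab$actions)
    sit <- sit + params$B[rest, vocab$index[["shivering"]] + 1L]
  s1 <- rest[which.max(sit)]
  s3 <- setdiff(rest, s1)
  map <- integer(3)
  map[s2] <- 2L; map[s1] <- 1L; map[s3] <- 3L
  structure(list(map = map), class = "state_label_map")
}

#' Relabel a raw decoded sequence with semantic states
#'
#' @param states A raw `state_sequence` from [viterbi_decode()].
#' @param map A `state_label_map` from [assign_semantic_labels()].
#' @return A semantic `state_sequence` with states in {1, 2, 3}.
#' @export
relabel <- function(states, map) {
  stopifnot(inherits(states, "state_sequence"),
            inherits(map, "state_label_map"))
  if (states$semantic)
    stop("sequence is already semantically labelled")
  raw <- states$states
  if (any(raw < 0 | raw >= length(map$map)))
    stop("raw state index outside the label map")
  state_sequence(map$map[raw + 1L], semantic = TRUE,
                 animal_id = states$animal_id, bin_s = states$bin_s,
                 t0 = states$t0)
}

#' Decoded state sequence
#'
#' @param states Integer vector: raw 0-based indices (`semantic = FALSE`)
#'   or semantic labels 1/2/3 (`semantic = TRUE`).
#' @param semantic Logical flag distinguishing the two encodings.
#' @param animal_id Animal identifier.
#' @param bin_s Bin width, seconds.
#' @param t0 Time of the first bin, seconds.
#' @return A `state_sequence` object.
#' @export
state_sequence <- function(states, semantic, animal_id = "animal",
                           bin_s = 1, t0 = 0) {
  states <- as.integer(states)
  if (length(states) == 0) stop("state sequence must be non-empty")
  if (semantic && !all(states %in% 1:3))
    stop("semantic states must be in {1, 2, 3}")
  if (!semantic && any(states < 0))
    stop("raw state indices must be >= 0")
  structure(list(states = states, semantic = isTRUE(semantic),
                 animal_id = as.character(animal_id),
                 bin_s = as.numeric(bin_s), t0 = as.numeric(t0)),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("State sequence '%s': %d bins (%s labels)\n", x$animal_id,
              length(x$states), if (x$semantic) "semantic" else "raw"))
  invisible(x)
}

#' @export
length.state_sequence <- function(x) length(x$states)

#' Write a fitted model to JSON
#'
#' @param fit An `hmm_fit` (or bare `hmm_params`).
#' @param path Output path.
#' @param vocab Vocabulary to store alongside.
#' @param label_map Optional `state_label_map`.
#' @return Invisibly, `path`.
#' @export
write_hmm_model <- function(fit, path, vocab = behavior_vocabulary(),
                            label_map = NULL) {
  if (inherits(fit, "hmm_params"))
    fit <- list(params = fit, loglik_trace = numeric(0), n_iter = 0L,
                converged = NA)
  obj <- list(pi = fit$params$pi,
              A = fit$params$A, B = fit$params$B,
              vocab = vocab$actions,
              label_map = if (!is.null(label_map)) label_map$map,
              n_iter = fit$n_iter, converged = fit$converged,
              loglik_trace = fit$loglik_trace)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path Path written by [write_hmm_model()].
#' @return List with `params` (`hmm_params`), `vocab`, `label_map` (or
#'   NULL) and fit metadata.
#' @export
read_hmm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- hmm_params(obj$pi, obj$A, obj$B)
  lm <- if (!is.null(obj$label_map))
    structure(list(map = as.integer(obj$label_map)),
              class = "state_label_map")
  list(params = params, vocab = behavior_vocabulary(obj$vocab),
       label_map = lm, n_iter = obj$n_iter, converged = obj$converged,
       loglik_trace = obj$loglik_trace)
}

# ---- internal helpers -------------------------------------------------

obs_codes <- function(obs, V) {
  codes <- if (inherits(obs, "observation_sequence")) obs$codes
           else as.integer(obs)
  if (length(codes) == 0) stop("empty observation sequence")
  if (any(codes < 0 | codes >= V))
    stop("observation codes must lie in [0, V-1]")
  codes
}

floor_renorm <- function(B, eps) {
  B[B < eps] <- eps
  B / rowSums(B)
}

first_impossible_step <- function(params, codes) {
  alpha <- params$pi * params$B[, codes[1] + 1L]
  if (sum(alpha) <= 0) return(1L)
  alpha <- alpha / sum(alpha)
  for (t in seq_along(codes)[-1]) {
    alpha <- as.numeric(alpha %*% params$A) * params$B[, codes[t] + 1L]
    if (sum(alpha) <= 0) return(t)
    alpha <- alpha / sum(alpha)
  }
  length(codes)  # unreachable when called on a -Inf path
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
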