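test_that("init_params starts from uniform transitions and a valid template", {
  p <- init_params(K = 3)
  expect_true(all(p$A == 1 / 3))
  expect_true(all(p$pi == 1 / 3))
  expect_equal(rowSums(p$B), rep(1, 3))

  p1 <- init_params(K = 1, vocab = behavior_vocabulary(c("a", "b")))
  expect_equal(p1$A, matrix(1))
  expect_equal(p1$pi, 1)

  j1 <- init_params(K = 3, jitter = 0.2, seed = 5)
  j2 <- init_params(K = 3, jitter = 0.2, seed = 5)
  expect_identical(j1$B, j2$B)
  expect_error(init_params(K = 2, vocab = behavior_vocabulary(c("a", "b")),
                           emission_template = matrix(0, 2, 2)),
               "zero row-sum")
})

test_that("forward likelihood matches direct products and enumeration", {
  # single state: likelihood is the product of emissions
  vab <- behavior_vocabulary(c("a", "b"))
  p1 <- hmm_params(1, matrix(1), matrix(c(0.8, 0.2), 1))
  expect_equal(forward_log_likelihood(p1, c(0L, 0L, 1L)),
               log(0.8 * 0.8 * 0.2))
  # T = 1 mixture collapses to the shared emission probability
  p2 <- hmm_params(c(.5, .5), matrix(.5, 2, 2),
                   rbind(c(.3, .7), c(.3, .7)))
  expect_equal(forward_log_likelihood(p2, 0L), log(0.3))
  # random instances vs brute-force path enumeration
  for (seed in 1:10) {
    p <- random_hmm(K = 3, V = 4, seed = seed)
    obs <- random_obs(V = 4, T = 5, seed = seed + 100)
    expect_equal(forward_log_likelihood(p, obs),
                 log(brute_force_likelihood(p$pi, p$A, p$B, obs + 1L)),
                 tolerance = 1e-10)
  }
  # zero-probability observation yields -Inf, not an error
  pz <- hmm_params(c(1, 0), rbind(c(1, 0), c(0, 1)),
                   rbind(c(1, 0), c(0, 1)))
  expect_identical(forward_log_likelihood(pz, c(0L, 1L)), -Inf)
})

test_that("one EM iteration reproduces hand-computed expected counts", {
  # K=1: M-step is symbol counting
  vab <- behavior_vocabulary(c("a", "b", "c"))
  p1 <- init_params(K = 1, vocab = vab)
  f1 <- baum_welch_fit(p1, c(0L, 0L, 1L, 2L, 0L), max_iter = 1)
  expect_equal(as.numeric(f1$params$B), c(3, 1, 1) / 5)

  # K=2, V=2, obs=(a,b,a): frozen values from an enumeration-based E/M
  # step computed independently (posterior-weighted path counts)
  p2 <- hmm_params(c(.5, .5), matrix(.5, 2, 2), rbind(c(.9, .1), c(.1, .9)))
  f2 <- baum_welch_fit(p2, c(0L, 1L, 0L), max_iter = 1)
  expect_equal(f2$params$pi, c(0.9, 0.1), tolerance = 1e-12)
  expect_equal(f2$params$A, rbind(c(0.18, 0.82), c(0.82, 0.18)),
               tolerance = 1e-12)
  expect_equal(f2$params$B, rbind(c(18 / 19, 1 / 19), c(2 / 11, 9 / 11)),
               tolerance = 1e-12)
  expect_equal(f2$loglik_trace, log(0.125), tolerance = 1e-12)
})

test_that("EM log-likelihood is monotone and rows stay stochastic", {
  for (seed in 1:20) {
    p0 <- random_hmm(K = 3, V = 5, seed = seed)
    obs <- random_obs(V = 5, T = 80, seed = seed + 500)
    fit <- baum_welch_fit(p0, obs, tol = 0, max_iter = 25)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_equal(rowSums(fit$params$A), rep(1, 3), tolerance = 1e-9)
    expect_equal(rowSums(fit$params$B), rep(1, 3), tolerance = 1e-9)
    expect_equal(sum(fit$params$pi), 1, tolerance = 1e-9)
  }
})

test_that("state posteriors sum to one at every time step", {
  p <- random_hmm(K = 3, V = 4, seed = 9)
  obs <- random_obs(V = 4, T = 200, seed = 10)
  fb <- coldstate:::cpp_forward_backward(p$pi, p$A, p$B, obs)
  expect_equal(rowSums(fb$gamma), rep(1, 200), tolerance = 1e-9)
  expect_equal(fb$loglik, forward_log_likelihood(p, obs))
})

test_that("Viterbi decodes forced paths, breaks ties low, matches enumeration", {
  # emissions partition the vocabulary: path is forced
  A <- matrix(1 / 3, 3, 3)
  B <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  p <- hmm_params(rep(1 / 3, 3), A, B)
  obs <- c(2L, 0L, 1L, 1L, 2L)
  expect_identical(viterbi_decode(p, obs)$states, c(2L, 0L, 1L, 1L, 2L))

  # all states identical: tie rule picks state 0 throughout
  pid <- hmm_params(rep(1 / 3, 3), matrix(1 / 3, 3, 3),
                    matrix(1 / 4, 3, 4))
  expect_identical(viterbi_decode(pid, c(0L, 3L, 2L))$states,
                   c(0L, 0L, 0L))

  # best-path score equals the enumeration maximum
  for (seed in 1:10) {
    p <- random_hmm(K = 3, V = 4, seed = seed + 40)
    obs <- random_obs(V = 4, T = 6, seed = seed + 140)
    dec <- viterbi_decode(p, obs)
    best <- brute_force_best_path(p$pi, p$A, p$B, obs + 1L)
    expect_equal(attr(dec, "logprob"), best, tolerance = 0)
    expect_equal(path_log_score(p$pi, p$A, p$B, obs + 1L,
                                dec$states + 1L),
                 best, tolerance = 0)
  }

  # impossible observation: error names the first impossible step
  pz <- hmm_params(c(1, 0), rbind(c(1, 0), c(0, 1)),
                   rbind(c(1, 0), c(0, 1)))
  expect_error(viterbi_decode(pz, c(0L, 0L, 1L)), "t = 3")
})

test_that("semantic labelling follows the eating-then-sitting rule", {
  v <- behavior_vocabulary()
  B <- default_emission_template(v)  # rows already in semantic order
  p <- hmm_params(rep(1 / 3, 3), matrix(1 / 3, 3, 3), B)
  expect_identical(assign_semantic_labels(p, v)$map, c(1L, 2L, 3L))

  # permuted rows are mapped back
  pp <- hmm_params(rep(1 / 3, 3), matrix(1 / 3, 3, 3), B[c(2, 3, 1), ])
  expect_identical(assign_semantic_labels(pp, v)$map, c(2L, 3L, 1L))

  # equal eating probability: lower index wins semantic state 2
  Bt <- matrix(1 / 15, 3, 15)
  pt <- hmm_params(rep(1 / 3, 3), matrix(1 / 3, 3, 3), Bt)
  expect_identical(assign_semantic_labels(pt, v)$map[1], 2L)

  expect_error(assign_semantic_labels(
    hmm_params(c(.5, .5), matrix(.5, 2, 2), matrix(1 / 15, 2, 15)), v),
    "3-state")
})

test_that("relabel maps raw indices once and only once", {
  m <- structure(list(map = c(1L, 2L, 3L)), class = "state_label_map")
  s <- state_sequence(c(0L, 0L, 1L), semantic = FALSE)
  r <- relabel(s, m)
  expect_identical(r$states, c(1L, 1L, 2L))
  expect_true(r$semantic)
  expect_error(relabel(r, m), "already semantically labelled")
  s2 <- state_sequence(c(0L, 5L), semantic = FALSE)
  expect_error(relabel(s2, m), "outside the label map")
})

test_that("model JSON round-trips parameters and label map", {
  path <- withr::local_tempfile(fileext = ".json")
  sim <- simulate_ethogram(duration_s = 400, n_animals = 1, seed = 2)
  fit <- baum_welch_fit(init_params(3),
                        encode_observations(sim$ethograms[[1]]))
  map <- assign_semantic_labels(fit$params)
  write_hmm_model(fit, path, label_map = map)
  back <- read_hmm_model(path)
  expect_equal(back$params$A, fit$params$A)
  expect_equal(back$params$B, fit$params$B, ignore_attr = TRUE)
  expect_identical(back$label_map$map, map$map)
  expect_equal(back$loglik_trace, fit$loglik_trace)
})
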