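test_that("network composition follows the 4:1 excitatory/inhibitory ratio", {
  p <- network_params()
  expect_identical(p$N_exc, 1600L)
  expect_identical(p$N_inh, 400L)
  expect_identical(p$N, 2000L)
  st <- build_network(p)
  expect_identical(dim(st$W), c(2000L, 2000L))
  # excitatory columns nonnegative, inhibitory columns nonpositive
  expect_true(all(st$W[, 1:1600] >= 0))
  expect_true(all(st$W[, 1601:2000] <= 0))
  # excitatory cells span regular-spiking..chattering (c in [-65,-50], d in [2,8])
  expect_true(all(st$c[1:1600] >= -65 & st$c[1:1600] <= -50))
  expect_true(all(st$d[1:1600] >= 2 & st$d[1:1600] <= 8))
  expect_error(network_params(N_exc = 0, N_inh = 0), "at least one")
})

test_that("build and run are bit-reproducible under a fixed seed", {
  p <- small_net(seed = 42)
  s1 <- build_network(p); s2 <- build_network(p)
  expect_identical(s1$W, s2$W)
  expect_identical(s1$a, s2$a)
  r1 <- run_network(s1, p); r2 <- run_network(s2, p)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$trace, r2$trace)
  # a different seed gives a different raster
  p3 <- small_net(seed = 43)
  r3 <- run_network(build_network(p3), p3)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("inhibitory_scale = 0 zeroes the inhibitory columns", {
  p <- small_net(inhibitory_scale = 0, seed = 5)
  st <- build_network(p)
  expect_true(all(st$W[, (p$N_exc + 1):p$N] == 0))
})

test_that("spiking runs clip recorded potentials at exactly 30 mV", {
  p <- small_net(seed = 8)
  r <- run_network(build_network(p), p)
  expect_gt(r$n_spikes, 0)
  expect_identical(r$max_v, 30)
  expect_lte(max(r$trace$v_mV), 30)
  expect_true(all(r$spikes$t_ms >= 0 & r$spikes$t_ms <= p$T))
  expect_true(all(r$spikes$neuron >= 1 & r$spikes$neuron <= p$N))
})

test_that("zero drive produces an empty raster and a zero synchrony index", {
  p <- small_net(drive_gain = 0, seed = 5)
  r <- run_network(build_network(p), p)
  expect_identical(r$n_spikes, 0L)
  expect_identical(synchrony_index(r), 0)
})

test_that("stronger thalamic drive never reduces the spike count", {
  for (seed in 1:3) {
    p1 <- small_net(seed = seed)
    p2 <- small_net(seed = seed, drive_gain = 1.5)
    n1 <- run_network(build_network(p1), p1)$n_spikes
    n2 <- run_network(build_network(p2), p2)$n_spikes
    expect_gte(n2, n1)
  }
})

test_that("synchrony index: coherent firing is maximal, shuffling destroys it", {
  p <- small_net(T = 500)
  # perfectly coherent synthetic raster: every neuron spikes in the same bins
  bins <- seq(5, 495, by = 50)
  coherent <- structure(
    list(spikes = data.frame(t_ms = rep(bins, each = p$N),
                             neuron = rep(seq_len(p$N), times = length(bins))),
         n_spikes = p$N * length(bins), params = p),
    class = "spike_raster")
  chi_coh <- synchrony_index(coherent, bin = 10)
  # every neuron has the identical binned series: population variance ratio 1
  expect_equal(chi_coh, 1)
  # independently shuffled spike times: permutation oracle, 100 shuffles
  set.seed(1)
  shuffled <- replicate(100, {
    r <- coherent
    r$spikes$t_ms <- runif(nrow(r$spikes), 0, p$T)
    synchrony_index(r, bin = 10)
  })
  expect_lt(median(shuffled), 0.05 * chi_coh)
  # invariant to neuron relabeling
  relab <- coherent
  perm <- sample(p$N)
  relab$spikes$neuron <- perm[relab$spikes$neuron]
  expect_equal(synchrony_index(relab, bin = 10), chi_coh)
  expect_error(synchrony_index(coherent, bin = 100), "T >= 10")
})

test_that("weak inhibition pushes the network into the synchronous regime", {
  p_async <- small_net(seed = 11)
  p_sync <- small_net(seed = 11, inhibitory_scale = 0.01)
  chi_a <- synchrony_index(run_network(build_network(p_async), p_async))
  chi_s <- synchrony_index(run_network(build_network(p_sync), p_sync))
  expect_gt(chi_s, chi_a)
})

test_that("a pinned memristive leak equals a fixed resistive leak exactly", {
  pinned <- memristor_params(flux_scale = 0)
  pa <- small_net(membrane_variant = "izhikevich_mc", memristor = pinned,
                  seed = 7)
  pb <- small_net(leak_R = 1e4, seed = 7)
  ra <- run_network(build_network(pa), pa)
  rb <- run_network(build_network(pb), pb)
  expect_identical(ra$spikes, rb$spikes)
  expect_identical(ra$trace, rb$trace)
  # a live flux changes the dynamics
  pc <- small_net(membrane_variant = "izhikevich_mc", seed = 7)
  rc <- run_network(build_network(pc), pc)
  expect_false(identical(rc$spikes, rb$spikes))
})
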