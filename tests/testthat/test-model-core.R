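test_that("default configurations carry the reference weight tables", {
  w <- function(cfg, role) unique(cfg$connections$weight[
    cfg$connections$role == role])
  k <- function(cfg, role) unique(cfg$connections$kind[
    cfg$connections$role == role])

  cfg <- network_config("all_types")
  expect_equal(w(cfg, "goal"), 3.2)
  expect_equal(w(cfg, "action"), 1.55)
  expect_equal(w(cfg, "self"), 1.7)
  expect_equal(w(cfg, "e_to_in"), 0.7)
  expect_equal(w(cfg, "in_to_e"), 5)
  expect_equal(k(cfg, "goal"), "depression")
  expect_equal(k(cfg, "action"), "facilitation")

  cfg <- network_config("depression_only")
  expect_equal(unname(vapply(c("goal", "action", "self", "e_to_in", "in_to_e"),
                             function(r) w(cfg, r), 0)),
               c(3, 0.5, 1.8, 0.7, 5.5))
  expect_equal(k(cfg, "goal"), "depression")
  expect_equal(k(cfg, "action"), "constant")

  cfg <- network_config("facilitation_only")
  expect_equal(unname(vapply(c("goal", "action", "self", "e_to_in", "in_to_e"),
                             function(r) w(cfg, r), 0)),
               c(0.8, 3.1, 1.9, 0.7, 7.5))
  expect_equal(k(cfg, "action"), "facilitation")
})

test_that("neuron and plasticity defaults match the reference parameter set", {
  ne <- neuron_params(TRUE); ni <- neuron_params(FALSE)
  expect_equal(c(ne$Vth, ne$Vreset, ne$VE, ne$VI), c(-52, -60, -5, -75))
  expect_equal(c(ne$Cm, ne$gL, ne$VL, ne$tref), c(0.5, 25, -70, 2))
  expect_equal(c(ni$Cm, ni$gL, ni$VL, ni$tref), c(0.2, 20, -65, 1))
  pl <- plasticity_params()
  expect_equal(pl$U, 0.2)
  expect_equal(c(pl$depression$tau_u, pl$depression$tau_x), c(20, 600))
  expect_equal(c(pl$facilitation$tau_u, pl$facilitation$tau_x), c(600, 100))
  expect_equal(c(pl$tau_s_exc, pl$tau_s_inh), c(100, 20))
  pr <- stimulus_protocol()
  expect_equal(c(pr$activation_amplitude, pr$activation_ramp), c(0.35, 200))
  expect_equal(c(pr$sensory_amplitude, pr$sensory_width), c(0.2, 200))
})

test_that("validation errors name the offending field", {
  cfg <- small_config()
  cfg$populations$A$neuron$tref <- -1
  expect_error(validate_config(cfg), "tref.*refractory|refractory")
  cfg <- small_config()
  cfg$plasticity$depression$tau_x <- -5
  expect_error(validate_config(cfg), "depression_tau_x")
  cfg <- small_config()
  cfg$populations$A$neuron$Vreset <- -40
  expect_error(validate_config(cfg), "Vreset")
  cfg <- small_config()
  cfg$connections$kind[cfg$connections$role == "goal"] <- "constant"
  expect_error(validate_config(cfg), "variant")
  cfg <- small_config()
  cfg$protocol$sensory_target <- "G3"
  expect_error(validate_config(cfg), "sensory_target")
})

test_that("network construction gives exact in-degree and summed weight", {
  cfg <- small_config(N = 50)
  net <- build_network(cfg, seed = 3)
  for (cl in net$classes) {
    expect_equal(cl$in_degree, round(0.2 * 50))
    expect_equal(nrow(cl$pre), cl$in_degree)
    # per-neuron summed weight equals the class summed weight
    role_w <- cfg$connections$weight[cfg$connections$pre == cl$pre_pop &
                                     cfg$connections$post == cl$post_pop]
    expect_equal(cl$weight_per_synapse * cl$in_degree, role_w,
                 tolerance = 1e-12)
    # sampling without replacement
    expect_true(all(apply(cl$pre, 2, anyDuplicated) == 0))
  }
  # self-recurrent classes exclude autapses
  self_cl <- Filter(function(cl) cl$pre_pop == cl$post_pop, net$classes)
  for (cl in self_cl) {
    off <- net$offset[[cl$pre_pop]]
    for (j in seq_len(ncol(cl$pre)))
      expect_false((off + j) %in% cl$pre[, j])
  }
})

test_that("all-to-all toy network divides the summed weight evenly", {
  cfg <- small_config(N = 10)
  cfg$connections$c_ratio[1] <- 1   # the A -> B class becomes all-to-all
  net <- build_network(validate_config(cfg), seed = 1)
  cl <- net$classes[[1]]   # A -> B, not self-recurrent
  expect_equal(cl$in_degree, 10)
  expect_equal(cl$weight_per_synapse, 3.2 / 10)
  expect_equal(sort(cl$pre[, 1]), net$offset[["A"]] + 1:10)
})

test_that("construction is deterministic in the seed and delays are uniform", {
  cfg <- small_config(N = 50)
  n1 <- build_network(cfg, seed = 11)
  n2 <- build_network(cfg, seed = 11)
  n3 <- build_network(cfg, seed = 12)
  expect_identical(n1$classes, n2$classes)
  expect_false(identical(n1$classes[[1]]$pre, n3$classes[[1]]$pre))
  expect_equal(n3$classes[[1]]$in_degree, n1$classes[[1]]$in_degree)

  big <- build_network(network_config("all_types", N = 200), seed = 5)
  delays <- unlist(lapply(big$classes, function(cl) as.numeric(cl$delay)))
  expect_gte(length(delays), 1e4)
  ks <- suppressWarnings(stats::ks.test(delays, "punif", 1, 5))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(delays >= 1 & delays <= 5))
})

test_that("cN rounding to zero partners is rejected", {
  cfg <- small_config(N = 2)
  expect_error(build_network(cfg), "zero presynaptic")
})

test_that("configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- network_config("depression_only", N = 80, noise_sigma = 0.21,
                        seed = 9L)
  cfg$connections$weight[1] <- 2.9
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$variant, "depression_only")
  expect_equal(back$populations$A$size, 80)
  expect_equal(back$noise_sigma, 0.21)
  expect_equal(back$connections$weight[1], 2.9)
  expect_equal(back$plasticity, cfg$plasticity)
  expect_equal(back$protocol, cfg$protocol)
})

test_that("canonical variant files reproduce the built-in tables", {
  for (v in c("all" = "all_types", "dep" = "depression_only",
              "fac" = "facilitation_only")) {
    f <- system.file("extdata", paste0("variant_",
      c(all_types = "all", depression_only = "dep",
        facilitation_only = "fac")[[v]], ".yaml"), package = "stpnet")
    expect_true(file.exists(f))
    cfg <- read_config(f)
    ref <- network_config(v)
    expect_identical(cfg$connections[c("pre", "post", "kind", "weight")],
                     ref$connections[c("pre", "post", "kind", "weight")])
  }
})
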