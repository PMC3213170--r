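#' Build a randomized network instance
#'
#' Draws the sparse connectivity: for every connection class each postsynaptic
#' neuron receives exactly `round(c * N_pre)` presynaptic partners, sampled
#' uniformly without replacement from the presynaptic population (excluding the
#' neuron itself within self-recurrent classes), with a per-synapse
#' transmission delay drawn uniformly from the class delay range.  The
#' per-synapse weight is the class summed weight divided by the in-degree, so
#' the summed input weight per neuron per class is exactly the configured
#' summed weight.
#'
#' @param config a validated `stp_config`.
#' @param seed integer; the draw is deterministic given the seed.
#' @return an object of class `stp_network`: the config plus, per connection
#'   class, the presynaptic index matrix (`in_degree` x `n_post`, global
#'   1-based indices), the matching delay matrix (ms) and the per-synapse
#'   weight.
#' @export
build_network <- function(config, seed = config$seed) {
  validate_config(config)
  sizes <- vapply(config$populations, function(p) as.integer(p$size),
                  integer(1))
  offset <- c(0, cumsum(sizes))[seq_along(sizes)]
  names(offset) <- names(sizes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cn <- config$connections
  classes <- vector("list", nrow(cn))
  for (i in seq_len(nrow(cn))) {
    pre_pop <- cn$pre[i]; post_pop <- cn$post[i]
    n_pre <- sizes[[pre_pop]]; n_post <- sizes[[post_pop]]
    indeg <- round(cn$c_ratio[i] * n_pre)
    if (indeg < 1) stop("connection ", pre_pop, "->", post_pop,
                        ": c*N rounds to zero presynaptic partners")
    self <- pre_pop == post_pop
    if (self && indeg > n_pre - 1)
      stop("connection ", pre_pop, "->", post_pop,
           ": in-degree exceeds available partners without autapses")
    pre <- matrix(0L, indeg, n_post)
    for (j in seq_len(n_post)) {
      pool <- if (self) setdiff(seq_len(n_pre), j) else seq_len(n_pre)
      pre[, j] <- sample(pool, indeg) + offset[[pre_pop]]
    }
    delay <- matrix(runif(indeg * n_post, cn$delay_min[i], cn$delay_max[i]),
                    indeg, n_post)
    classes[[i]] <- list(pre_pop = pre_pop, post_pop = post_pop,
                         kind = cn$kind[i], role = cn$role[i],
                         weight_per_synapse = cn$weight[i] / indeg,
                         in_degree = indeg, pre = pre, delay = delay)
  }
  structure(list(config = config, sizes = sizes, offset = offset,
                 classes = classes, seed = as.integer(seed)),
            class = "stp_network")
}

#' @export
print.stp_network <- function(x, ...) {
  cat("stp_network:", x$config$variant, "-",
      sum(x$sizes), "neurons,", length(x$classes), "connection classes\n")
  invisible(x)
}

# Preserve the caller's RNG state around internally seeded draws.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
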