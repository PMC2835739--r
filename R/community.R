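# Seeded random community generation and prescribed ecotype pairs.

#' Default trait sampling ranges
#'
#' Per-size-class `[low, high]` intervals for every physiological trait,
#' loaded from the versioned table shipped with the package. Intervals for
#' `mu_max` and the N/P half-saturations are disjoint between size classes,
#' so every generated community satisfies the small-versus-large ordering
#' contract (picophytoplankton grow slower but at lower nutrient levels).
#'
#' @return Nested list `ranges$small$<trait> = c(low, high)`, idem `large`.
#' @export
default_trait_ranges <- function() {
  tr <- jsonlite::read_json(.extdata("trait_ranges.json"),
                            simplifyVector = TRUE)
  tr[c("small", "large")]
}

.validate_ranges <- function(ranges) {
  for (cls in c("small", "large")) {
    if (is.null(ranges[[cls]])) stop("ranges must have '", cls, "' entry")
    for (col in .TRAIT_COLS) {
      iv <- ranges[[cls]][[col]]
      if (is.null(iv) || length(iv) != 2 || any(!is.finite(iv)))
        stop("invalid range for field '", col, "' (", cls, ")")
      if (iv[1] > iv[2])
        stop("range low > high for field '", col, "' (", cls, ")")
    }
  }
  for (col in c("mu_max", "K_NH4", "K_NO2", "K_NO3", "K_PO4"))
    if (ranges$small[[col]][2] >= ranges$large[[col]][1])
      stop("small/large intervals must be disjoint for field '", col,
           "' (small high must be below large low)")
  ranges
}

#' Generate a random phytoplankton community
#'
#' Draws `n_small` picophytoplankton and `n_large` large-phytoplankton types
#' with traits sampled uniformly and independently within the configured
#' intervals. Deterministic given `seed`. All generated parents can use
#' nitrate, nitrite and ammonium.
#'
#' @param ranges Trait intervals, see [default_trait_ranges()].
#' @param n_small,n_large Number of types per size class (defaults 15 and 18).
#' @param seed Integer seed for the draw.
#' @return A `phyto_community` data.frame with `n_small + n_large` rows.
#' @export
generate_community <- function(ranges = default_trait_ranges(),
                               n_small = 15, n_large = 18, seed = 1) {
  stopifnot(n_small >= 1, n_large >= 0)
  .validate_ranges(ranges)
  draw <- function(cls, n, prefix) {
    cols <- lapply(.TRAIT_COLS, function(col) {
      iv <- ranges[[cls]][[col]]
      runif(n, iv[1], iv[2])
    })
    names(cols) <- .TRAIT_COLS
    data.frame(id = sprintf("%s%02d", prefix, seq_len(n)),
               size_class = cls, cols, can_NO3 = TRUE, can_NO2 = TRUE,
               stringsAsFactors = FALSE)
  }
  com <- withr_seed(seed, {
    rbind(draw("small", n_small, "pico"),
          if (n_large > 0) draw("large", n_large, "large"))
  })
  class(com) <- c("phyto_community", "data.frame")
  validate_community(com)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Prescribed ecotype pair for succession experiments
#'
#' A controlled contrast between a warm-water picophytoplankter ("E2", the
#' high-light Prochlorococcus-like analog) and a cold-water one ("E3", the
#' Synechococcus-like analog): E2 has a higher optimum growth temperature and
#' slightly lower nutrient half-saturations than E3; every other trait is
#' identical. Under seasonal mixed-layer forcing E2 dominates the stratified
#' summer (warm, recycled ammonium) and E3 blooms around deep winter mixing
#' when entrained nitrate is abundant.
#'
#' @param style Pair style; only `"E2_E3"` is defined.
#' @return A two-row `phyto_community` (ids `"E2"`, `"E3"`).
#' @export
make_ecotype_pair <- function(style = "E2_E3") {
  if (!identical(style, "E2_E3"))
    stop("unknown ecotype pair style '", style, "'; available: E2_E3")
  shared <- list(size_class = "small", mu_max = 0.8, T_width = 4,
                 I_opt = 30, k_inhib = 0.001, K_Fe = 0.2, psi = 1.5,
                 R_FeP = 1.5, mortality = 0.03, palatability = 1)
  e2 <- do.call(phyto_traits, c(list(id = "E2", T_opt = 22, K_NH4 = 0.10,
                                     K_NO2 = 0.15, K_NO3 = 0.15,
                                     K_PO4 = 0.006), shared))
  e3 <- do.call(phyto_traits, c(list(id = "E3", T_opt = 16, K_NH4 = 0.12,
                                     K_NO2 = 0.18, K_NO3 = 0.18,
                                     K_PO4 = 0.0075), shared))
  com <- rbind(e2, e3)
  class(com) <- c("phyto_community", "data.frame")
  validate_community(com)
}

#' Deterministic ensemble seeds
#'
#' Expands a base seed into `n` distinct member seeds (used to initialize
#' ensembles of randomly generated communities).
#'
#' @param base_seed Integer.
#' @param n Number of members (default 10).
#' @return Integer vector of length `n`, distinct, deterministic.
#' @export
ensemble_seeds <- function(base_seed, n = 10) {
  stopifnot(n >= 1)
  as.integer(base_seed) + 1013L * seq_len(n)
}

#' Read or write a community table as JSON
#'
#' A generated community file is a valid simulation input, so a run can be
#' reproduced without re-drawing traits.
#'
#' @param com A `phyto_community`.
#' @param path File path.
#' @return `read_community` returns a `phyto_community`; `write_community`
#'   returns `path` invisibly.
#' @export
write_community <- function(com, path) {
  validate_community(com)
  jsonlite::write_json(as.data.frame(com), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_community
#' @export
read_community <- function(path) {
  com <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_community(com)
}
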