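# Independent oracles used to freeze expected values: a naive full-lattice
# decomposition enumerator with its own mass table and filter arithmetic,
# kept deliberately separate from the package implementation.

ORACLE_MASSES <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.9737615120, S = 31.9720706912, Si = 27.9769265327
)
ORACLE_VALENCE <- c(C = 4, H = 1, N = 3, O = 2, P = 3, S = 2, Si = 4)
ORACLE_ELECTRON <- 0.000548579909

# brute-force enumeration over the full (H included) lattice
oracle_decompose <- function(mass, cons, as_fragment_ion = FALSE) {
  els <- names(cons$element_max)
  target <- if (as_fragment_ion) mass + ORACLE_ELECTRON else mass
  lo <- target * (1 - cons$tolerance_ppm * 1e-6)
  hi <- target * (1 + cons$tolerance_ppm * 1e-6)
  grid <- do.call(expand.grid, lapply(els, function(e) {
    seq.int(cons$element_min[[e]], cons$element_max[[e]])
  }))
  names(grid) <- els
  gm <- as.matrix(grid)
  m <- as.vector(gm %*% ORACLE_MASSES[els])
  keep <- m >= lo & m <= hi & rowSums(gm) > 0
  gm <- gm[keep, , drop = FALSE]
  if (!nrow(gm)) {
    return(character(0))
  }
  all_els <- c("C", "H", "N", "O", "P", "S", "Si")
  full <- matrix(0L, nrow(gm), length(all_els), dimnames = list(NULL, all_els))
  full[, colnames(gm)] <- gm
  rd <- 1 + as.vector(full %*% (ORACLE_VALENCE - 2)) / 2
  vs <- as.vector(full %*% ORACLE_VALENCE)
  na <- rowSums(full)
  ok <- rd >= cons$rdbe_range[1] & rd <= cons$rdbe_range[2]
  if (!as_fragment_ion && !cons$allow_half_integer_rdbe) {
    ok <- ok & (rd %% 1 == 0)
  }
  if (!as_fragment_ion && cons$senior) {
    ok <- ok & (vs %% 2 == 0) & (vs >= 2 * (na - 1))
  }
  if (cons$ratio_check) {
    cc <- full[, "C"] + full[, "Si"]
    rl <- cons$ratio_limits
    rat_ok <- rep(TRUE, nrow(full))
    has_c <- cc > 0
    rat_ok[has_c] <-
      full[has_c, "H"] / cc[has_c] >= rl$h_c[1] &
        full[has_c, "H"] / cc[has_c] <= rl$h_c[2] &
        full[has_c, "N"] / cc[has_c] <= rl$n_c[2] &
        full[has_c, "O"] / cc[has_c] <= rl$o_c[2] &
        full[has_c, "P"] / cc[has_c] <= rl$p_c[2] &
        full[has_c, "S"] / cc[has_c] <= rl$s_c[2]
    ok <- ok & rat_ok
  }
  full <- full[ok, , drop = FALSE]
  if (!nrow(full)) {
    return(character(0))
  }
  sort(apply(full, 1L, function(cnt) {
    nz <- cnt[cnt > 0]
    paste0(names(nz), ifelse(nz == 1, "", nz), collapse = "")
  }))
}

# random (mass, constraints) draw with bounded lattice size
draw_decomposition_case <- function(max_lattice = 1e6) {
  repeat {
    els <- c("C", "H", sample(c("N", "O", "P", "S", "Si"), sample(1:3, 1)))
    maxes <- stats::setNames(
      vapply(els, function(e) {
        if (e == "C") {
          sample(5:20, 1)
        } else if (e == "H") sample(10:40, 1) else sample(1:6, 1)
      }, numeric(1)),
      els
    )
    if (prod(maxes + 1) > max_lattice) next
    frag <- stats::runif(1) < 0.4
    cons <- decomposition_constraints(
      tolerance_ppm = stats::runif(1, 2, 10),
      element_max = maxes,
      rdbe_range = c(-0.5, 40),
      senior = stats::runif(1) < 0.7,
      ratio_check = stats::runif(1) < 0.7
    )
    mass <- stats::runif(1, 60, 450)
    return(list(mass = mass, cons = cons, frag = frag))
  }
}

# convenience spectrum builders
unit_spec <- function(mz, intensity, id = "q", ...) {
  msp_spectrum(mz, intensity, id = id, resolution = "unit", ...)
}
acc_spec <- function(mz, intensity, id = "q", ...) {
  msp_spectrum(mz, intensity, id = id, resolution = "accurate", ...)
}

# two-group feature data with optional planted fold changes
sim_groups <- function(n_cmp, n_per = 5, planted = integer(0), fc = 4,
                       cv = 0.1, seed = 71) {
  set.seed(seed)
  cls <- c(
    stats::setNames(rep("control", n_per), sprintf("c%02d", 1:n_per)),
    stats::setNames(rep("stress", n_per), sprintf("s%02d", 1:n_per))
  )
  areas <- lapply(seq_len(n_cmp), function(i) {
    mu <- 10^stats::runif(1, 4, 6)
    mult <- ifelse(
      names(cls) %in% sprintf("s%02d", 1:n_per) & i %in% planted,
      fc, 1
    )
    stats::rlnorm(length(cls), log(mu * mult), sqrt(log(1 + cv^2)))
  })
  names(areas) <- sprintf("cmp%03d", seq_len(n_cmp))
  make_feature_data(areas, cls)
}

# minimal feature-data constructor for filter tests
make_feature_data <- function(compound_areas, classes, orders = NULL) {
  samples <- names(classes)
  if (is.null(orders)) orders <- seq_along(samples)
  purrr::map_dfr(names(compound_areas), function(cmp) {
    tibble::tibble(
      compound = cmp,
      sample = samples,
      class = unname(classes),
      injection_order = orders,
      area = compound_areas[[cmp]]
    )
  })
}
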