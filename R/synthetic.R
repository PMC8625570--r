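#' Ground-truth kinetic fixture table
#'
#' Deterministic table of rate constants used to drive the trace
#' simulators and to validate the estimation pipeline. Kd values and Kd
#' ratios are anchored to the published kinetics of the IQGAP1 C794
#' fragment (RAC2 Kd 27 nM; RAC1 34-fold weaker, split 4.25-fold on kon
#' and 8-fold on koff; CDC42 3-fold tighter than RAC1; the GRD-CDC42Q61L
#' pair at 2.37 µM; RAC1 hotspot variants 7- to 17-fold weaker than
#' RAC1); absolute kon scales are package choices in the typical
#' effector range of 1-10 per µM per s. Each entry records its
#' provenance.
#'
#' @return Named list; each entry has `rates` ([rate_constants()]) and
#'   `provenance` (character).
#' @examples
#' make_kinetics_fixture()$rac2$rates
#' @export
make_kinetics_fixture <- function() {
  kon_rac2 <- 8; koff_rac2 <- 0.216           # Kd 27 nM
  kon_rac1 <- kon_rac2 / 4.25                 # 4.25-fold slower on
  koff_rac1 <- koff_rac2 * 8                  # 8-fold faster off
  kd_rac1 <- koff_rac1 / kon_rac1             # 34 x 27 nM = 0.918 uM
  kd_cdc42 <- kd_rac1 / 3                     # 3-fold tighter than RAC1
  anchored <- "anchored-to-paper ratio, absolute scale invented"
  entry <- function(kon, koff, provenance) {
    list(rates = rate_constants(kon, koff), provenance = provenance)
  }
  list(
    rac2 = entry(kon_rac2, koff_rac2, anchored),
    rac1 = entry(kon_rac1, koff_rac1, anchored),
    cdc42 = entry(3, 3 * kd_cdc42, anchored),
    rac3 = entry(1.6, 1.6 * kd_rac1 * 1.05,
                 "binder with RAC1-like affinity; values invented"),
    rhog = entry(1.2, 1.2 * kd_rac1 * 1.2,
                 "binder with RAC1-like affinity; values invented"),
    grd_cdc42q61l = entry(1, 2.37, anchored),
    rac1_T25K_N26D = entry(kon_rac1 / 2.5, koff_rac1 * 4, anchored),
    rac1_M45E_N52E = entry(kon_rac1 / 2, koff_rac1 * 3.5, anchored),
    rac1_Q74D = entry(kon_rac1 / 4, koff_rac1 * 4.25, anchored),
    rac1_V85D_S88D = entry(kon_rac1 / 3, koff_rac1 * 4, anchored)
  )
}

#' Generate a seeded association/displacement trace set
#'
#' Emulates one complete stopped-flow measurement series for a fixture
#' entry: association traces of 0.2 µM labelled GTPase at each effector
#' concentration plus one displacement trace at 10 µM unlabelled
#' displacer, all with seeded Gaussian noise.
#'
#' @param entry Fixture entry name (see [make_kinetics_fixture()]) or a
#'   [rate_constants()] object.
#' @param concentrations Effector concentrations (µM).
#' @param sigma Noise level (fraction of signal span).
#' @param seed Base seed; each trace uses a distinct derived seed.
#' @param mix Base [mix_config()].
#' @return List with `association` (list of traces named by
#'   concentration) and `displacement` (one trace).
#' @export
generate_trace_set <- function(entry, concentrations = c(2, 4, 6, 8),
                               sigma = 0.02, seed = 1L,
                               mix = mix_config()) {
  if (is.character(entry)) {
    fixture <- make_kinetics_fixture()
    if (!entry %in% names(fixture)) {
      stop("unknown fixture entry '", entry, "'", call. = FALSE)
    }
    rates <- fixture[[entry]]$rates
  } else {
    rates <- entry
  }
  association <- lapply(seq_along(concentrations), function(j) {
    m <- mix; m$E0 <- concentrations[j]
    simulate_association(rates, m, sigma, seed = seed * 1000L + j)
  })
  names(association) <- as.character(concentrations)
  # displacement premix: equimolar pre-formed complex (free effector
  # excess would add a rebinding phase on top of the dissociation)
  m <- mix; m$E0 <- mix$R0
  displacement <- simulate_displacement(rates, m, sigma,
                                        seed = seed * 1000L + 99L)
  list(association = association, displacement = displacement)
}

#' Specification of a planted toy alignment
#'
#' @param n_binders,n_nonbinders Row counts per label.
#' @param length Alignment length (columns = reference positions).
#' @param planted data.frame with columns `position`, `binder`,
#'   `nonbinder`: columns where all binders carry `binder` and all
#'   nonbinders carry `nonbinder`.
#' @param background Residue filling all other columns identically.
#' @param variable_columns Columns drawn per-row from a seeded uniform
#'   choice of polar residues (never candidates: variable within the
#'   binders themselves).
#' @param excluded Excluded region set declared by this specification
#'   (planted positions must lie outside); defaults to
#'   [switch_regions()].
#' @param seed Seed for the variable columns.
#' @return A `ToyAlignmentSpec` list.
#' @export
toy_alignment_spec <- function(n_binders = 5L, n_nonbinders = 8L,
                               length = 100L,
                               planted = data.frame(
                                 position = c(10L, 50L, 90L),
                                 binder = "M", nonbinder = "E"),
                               background = "A",
                               variable_columns = c(24L, 27L),
                               excluded = switch_regions(),
                               seed = 1L) {
  stopifnot(n_binders >= 1L, n_nonbinders >= 1L, length >= 1L)
  if (nrow(planted) > 0L) {
    if (any(planted$position < 1L | planted$position > length)) {
      stop("planted positions outside the alignment", call. = FALSE)
    }
    if (any(in_regions(planted$position, excluded))) {
      stop("planted positions fall inside the excluded regions",
           call. = FALSE)
    }
  }
  list(n_binders = as.integer(n_binders),
       n_nonbinders = as.integer(n_nonbinders),
       length = as.integer(length), planted = planted,
       background = background,
       variable_columns = as.integer(variable_columns),
       excluded = excluded, seed = as.integer(seed))
}

#' Generate a labelled toy alignment with planted discriminating columns
#'
#' Binders carry the binder residue and nonbinders the nonbinder residue
#' at every planted column; variable columns are drawn per-row from a
#' seeded uniform choice; all remaining columns are identical across
#' rows. The first binder row is the numbering reference (gapless, so
#' reference positions equal columns).
#'
#' @param spec A [toy_alignment_spec()].
#' @return An [alignment_set()].
#' @export
generate_toy_alignment <- function(spec = toy_alignment_spec()) {
  set.seed(spec$seed)
  variable_pool <- c("S", "T", "N", "Q")
  n <- spec$n_binders + spec$n_nonbinders
  labels <- rep(c("binder", "nonbinder"),
                c(spec$n_binders, spec$n_nonbinders))
  rows <- vapply(seq_len(n), function(i) {
    chars <- rep(spec$background, spec$length)
    if (nrow(spec$planted) > 0L) {
      chars[spec$planted$position] <-
        if (labels[i] == "binder") spec$planted$binder
        else spec$planted$nonbinder
    }
    if (length(spec$variable_columns) > 0L) {
      chars[spec$variable_columns] <-
        sample(variable_pool, length(spec$variable_columns),
               replace = TRUE)
    }
    paste(chars, collapse = "")
  }, character(1))
  ids <- c(paste0("binder", seq_len(spec$n_binders)),
           paste0("nonbinder", seq_len(spec$n_nonbinders)))
  records <- lapply(seq_len(n), function(i) {
    sequence_record(ids[i], rows[i], label = labels[i])
  })
  alignment_set(records, rows, reference_id = ids[1L])
}

#' Generate a synthetic SEC elution profile
#'
#' Sum of Gaussian peaks on a 0.02-mL grid spanning the column volume,
#' plus seeded Gaussian noise.
#'
#' @param peaks data.frame with columns `Ve_ml`, `height`, `width_ml`
#'   (Gaussian sd); centres must lie inside `[V0, Vc]`.
#' @param noise Noise standard deviation (absorbance units).
#' @param seed Seed for the noise.
#' @param geometry A [column_geometry()].
#' @return data.frame with columns `volume_ml`, `absorbance`.
#' @export
generate_elution_profile <- function(peaks, noise = 0, seed = 1L,
                                     geometry = column_geometry()) {
  grid <- seq(geometry$V0, geometry$Vc, by = 0.02)
  absorbance <- rep(0, length(grid))
  if (nrow(peaks) > 0L) {
    if (any(peaks$Ve_ml < geometry$V0 | peaks$Ve_ml > geometry$Vc)) {
      stop("peak centre outside the column volume", call. = FALSE)
    }
    for (i in seq_len(nrow(peaks))) {
      absorbance <- absorbance + peaks$height[i] *
        exp(-(grid - peaks$Ve_ml[i])^2 / (2 * peaks$width_ml[i]^2))
    }
  }
  if (noise > 0) {
    set.seed(as.integer(seed))
    absorbance <- absorbance + rnorm(length(grid), 0, noise)
  }
  data.frame(volume_ml = grid, absorbance = absorbance)
}

#' Generate a toy two-chain complex with a controlled interface
#'
#' Builds two chains (A and B) of single-carbon pseudo-residues with
#' exactly `n_contact_pairs` heavy-atom pairs at `separation` Angstrom
#' (below the 4.5 A contact cutoff) and all other inter-chain pairs
#' beyond 8 A. Seeded jitter displaces each contact pair rigidly so the
#' pair distance is preserved.
#'
#' @param n_contact_pairs Number of contacting residue pairs (>= 0).
#' @param separation Distance of each contact pair (Angstrom, must be in
#'   (0, 4.5) for the pairs to count as contacts).
#' @param n_far Additional non-contacting residues per chain.
#' @param seed Seed for the jitter.
#' @return An atom data.frame in the layout of [read_structure()].
#' @export
generate_toy_complex <- function(n_contact_pairs, separation = 4.0,
                                 n_far = 2L, seed = 1L) {
  if (separation <= 0) stop("separation must be positive", call. = FALSE)
  if (separation >= 4.5) {
    stop("infeasible geometry: contact pairs must be closer than 4.5 A",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  rows <- list()
  add <- function(chain, resno, x, y, z) {
    data.frame(chain = chain, resno = resno, resid = "GLY",
               atom = "CA", x = x, y = y, z = z, element = "C",
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_contact_pairs)) {
    jit <- runif(2, -0.3, 0.3)
    y <- 20 * i + jit[1L]; z <- jit[2L]
    rows[[length(rows) + 1L]] <- add("A", i, 0, y, z)
    rows[[length(rows) + 1L]] <- add("B", i, separation, y, z)
  }
  for (i in seq_len(n_far)) {
    rows[[length(rows) + 1L]] <-
      add("A", 100L + i, -40, 20 * i + runif(1, -0.3, 0.3), 0)
    rows[[length(rows) + 1L]] <-
      add("B", 100L + i, 40 + separation,
          20 * i + runif(1, -0.3, 0.3), 0)
  }
  if (length(rows) == 0L) {
    stop("empty complex requested: need contact pairs or far residues",
         call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a toy complex to a PDB file
#'
#' @param atoms Atom data.frame (e.g. from [generate_toy_complex()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(atoms, path) {
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = atoms$resno, resid = atoms$resid,
                   chain = atoms$chain, elety = atoms$atom,
                   elesy = atoms$element)
  invisible(path)
}

#' Synthetic SEC calibration standards
#'
#' A typical gel-filtration standard set (13.7-669 kDa) with elution
#' volumes generated from a constructed calibration line
#' `Kav = -0.38 log10(mass) + 1.1` on the default 8/24-mL column. The
#' real column calibration of the original experiments is not public;
#' this synthetic set exercises the calibration arithmetic.
#'
#' @return data.frame with columns `name`, `mass_kda`, `Ve_ml`.
#' @export
synthetic_calibration_standards <- function() {
  standards <- data.frame(
    name = c("ribonuclease_a", "carbonic_anhydrase", "ovalbumin",
             "conalbumin", "aldolase", "ferritin", "thyroglobulin"),
    mass_kda = c(13.7, 29, 44, 75, 158, 440, 669)
  )
  geometry <- column_geometry()
  k <- -0.38 * log10(standards$mass_kda) + 1.1
  standards$Ve_ml <- round(geometry$V0 + k * (geometry$Vc - geometry$V0),
                           2)
  standards
}
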