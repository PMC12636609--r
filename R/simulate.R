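# All generators are deterministic given `seed` (withr::with_seed), and leave
# the caller's RNG state untouched.

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code() else withr::with_seed(seed, code())
}

place_nonoverlapping <- function(n, width, genome, max_tries = 10000) {
  placed <- tibble(chrom = character(), start = numeric(), end = numeric())
  tries <- 0
  while (nrow(placed) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      abort("genome too small to place regions without overlap")
    }
    ok <- genome$length >= width
    if (!any(ok)) abort("genome too small for the region width")
    j <- if (sum(ok) == 1) which(ok) else sample(which(ok), 1,
                                                 prob = genome$length[ok])
    s <- floor(runif(1) * (genome$length[j] - width + 1))
    clash <- placed$chrom == genome$chrom[j] &
      placed$start < s + width & s < placed$end
    if (!any(clash)) {
      placed <- dplyr::bind_rows(placed, tibble(chrom = genome$chrom[j],
                                                start = s, end = s + width))
    }
  }
  placed
}

# one interactome interval of `width` bp overlapping region [s, e) by >= 1 bp
overlap_interval <- function(chrom, s, e, width, genome) {
  L <- genome$length[match(chrom, genome$chrom)]
  lo <- max(0, s - width + 1)
  hi <- min(e - 1, L - width)
  start <- floor(runif(1) * (hi - lo + 1)) + lo
  c(start, start + width)
}

#' Simulate a planted rG4 x interactome enrichment dataset
#'
#' Emulates the inputs of the transcriptome-interval enrichment analysis:
#' scored 30-bp rG4 regions placed without self-overlap in a small genome,
#' and soluble/droplet interactome interval sets (100 bp) planted to
#' overlap each region with stratum-dependent probabilities, so that the
#' high-probability stratum is enriched in the soluble phase. A number of
#' regions can be made soluble-exclusive (droplet probability forced to 0
#' and the soluble overlap forced on, so the planted label is recoverable).
#' Setting all plant probabilities to 0 with `n_background > 0` yields a
#' null dataset in which interactome intervals are independent of the
#' regions (the calibration configuration).
#'
#' @param n_g4 Number of rG4 regions (default 300, >= 3).
#' @param genome Genome table (default two 1-Mbp chromosomes).
#' @param region_width rG4 region width in bp (default 30).
#' @param interactome_width Interactome interval width in bp (default 100).
#' @param p_soluble_high,p_soluble_medium,p_soluble_low Per-region
#'   probability of a planted soluble-interactome overlap by stratum
#'   (defaults 0.8 / 0.55 / 0.3).
#' @param p_droplet Per-region probability of a planted droplet overlap
#'   (default 0.3, all strata).
#' @param n_exclusive Number of high-stratum regions forced soluble-only
#'   (default 1).
#' @param n_background Uniformly placed interactome intervals added to
#'   each phase, independent of the regions (default 0).
#' @param seed Integer seed.
#' @return A list with `genome`, `regions` (intervals +
#'   `g4_probability` + `stratum`), `soluble`, `droplet` (interval
#'   tibbles) and `truth` (per-region planted flags).
#' @export
simulate_enrichment_dataset <- function(n_g4 = 300,
                                        genome = genome_table(
                                          c("chr1", "chr2"), c(1e6, 1e6)),
                                        region_width = 30,
                                        interactome_width = 100,
                                        p_soluble_high = 0.8,
                                        p_soluble_medium = 0.55,
                                        p_soluble_low = 0.3,
                                        p_droplet = 0.3,
                                        n_exclusive = 1,
                                        n_background = 0,
                                        seed = NULL) {
  if (n_g4 < 3) abort("n_g4 must be >= 3")
  probs <- c(p_soluble_high, p_soluble_medium, p_soluble_low, p_droplet)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  with_seed_maybe(seed, function() {
    regions <- place_nonoverlapping(n_g4, region_width, genome)
    regions$name <- sprintf("g4_%04d", seq_len(n_g4))
    regions$score <- NA_real_
    regions$strand <- "."
    regions$g4_probability <- runif(n_g4)
    regions <- stratify_by_probability(regions)

    p_sol <- c(low = p_soluble_low, medium = p_soluble_medium,
               high = p_soluble_high)[as.character(regions$stratum)]
    planted_soluble <- runif(n_g4) < p_sol
    planted_droplet <- runif(n_g4) < p_droplet
    is_exclusive <- rep(FALSE, n_g4)
    if (n_exclusive > 0) {
      high_idx <- which(regions$stratum == "high")
      if (length(high_idx) < n_exclusive) {
        abort("not enough high-stratum regions for n_exclusive")
      }
      excl <- high_idx[order(-regions$g4_probability[high_idx])][
        seq_len(n_exclusive)]
      is_exclusive[excl] <- TRUE
      planted_soluble[excl] <- TRUE   # guarantee the soluble_only label
      planted_droplet[excl] <- FALSE
    }

    make_set <- function(flags, prefix) {
      rows <- lapply(which(flags), function(i) {
        se <- overlap_interval(regions$chrom[i], regions$start[i],
                               regions$end[i], interactome_width, genome)
        tibble(chrom = regions$chrom[i], start = se[1], end = se[2])
      })
      planted <- dplyr::bind_rows(rows)
      bg <- if (n_background > 0) {
        tmp <- shuffle_intervals_impl(
          genomic_intervals(rep(genome$chrom[1], n_background),
                            rep(0, n_background),
                            rep(interactome_width, n_background)),
          genome)
        tmp[, c("chrom", "start", "end")]
      } else NULL
      out <- dplyr::bind_rows(planted, bg)
      if (nrow(out) == 0) {
        return(genomic_intervals(character(), numeric(), numeric()))
      }
      genomic_intervals(out$chrom, out$start, out$end,
                        name = sprintf("%s_%04d", prefix, seq_len(nrow(out))))
    }
    soluble <- make_set(planted_soluble, "sol")
    droplet <- make_set(planted_droplet, "drop")

    list(genome = genome, regions = regions, soluble = soluble,
         droplet = droplet,
         truth = tibble(name = regions$name,
                        stratum = regions$stratum,
                        planted_soluble = planted_soluble,
                        planted_droplet = planted_droplet,
                        is_exclusive = is_exclusive))
  })
}

#' Simulate an anisotropy titration curve
#'
#' Evaluates [binding_model()] on a log-spaced protein grid and adds
#' i.i.d. Gaussian noise.
#'
#' @param delta_a_max,k_d,l_t,a0 Model parameters (see [binding_model()]);
#'   defaults mirror a typical nanomolar FUS-RNA titration at 8 nM
#'   labelled RNA.
#' @param n Number of titration points (default 12).
#' @param sigma Gaussian noise sd on anisotropy (default 0.002).
#' @param x Optional protein grid (nM); default log-spaced from
#'   `k_d/100` to `200*k_d`.
#' @param seed Integer seed.
#' @return Curve tibble (`series`, `x`, `y`).
#' @export
simulate_titration <- function(delta_a_max = 0.1, k_d = 50, l_t = 8,
                               a0 = 0.05, n = 12, sigma = 0.002,
                               x = NULL, seed = NULL) {
  if (sigma < 0) abort("sigma must be >= 0")
  if (is.null(x)) {
    x <- 10^seq(log10(k_d / 100), log10(k_d * 200), length.out = n)
  }
  with_seed_maybe(seed, function() {
    tibble(series = "titration", x = x,
           y = binding_model(x, delta_a_max, k_d, l_t, a0) +
             rnorm(length(x), sd = sigma))
  })
}

#' Simulate a CD melt curve
#'
#' Evaluates [melt_model()] on the standard melt grid (15-85 C at 1 C
#' pitch) and adds Gaussian noise. Defaults are the potassium-buffer
#' fixture for the archetypal strong-inhibitor rG4: Tm 50.64 C, van't Hoff
#' enthalpy 180 kJ/mol, flat baselines at 6 and 1 mdeg (folded parallel-G4
#' signal at 265 nm decaying to a small unfolded residual).
#'
#' @param tm_celsius Melting temperature (C).
#' @param delta_h van't Hoff enthalpy (J/mol).
#' @param m_folded,b_folded,m_unfolded,b_unfolded Baselines (mdeg/K, mdeg).
#' @param t_min,t_max,pitch Temperature grid (C).
#' @param sigma Gaussian noise sd (mdeg).
#' @param seed Integer seed.
#' @return Curve tibble (`series`, `x` = temperature C, `y` = mdeg).
#' @export
simulate_melt <- function(tm_celsius = 50.64, delta_h = 180e3,
                          m_folded = 0, b_folded = 6,
                          m_unfolded = 0, b_unfolded = 1,
                          t_min = 15, t_max = 85, pitch = 1,
                          sigma = 0.1, seed = NULL) {
  if (sigma < 0) abort("sigma must be >= 0")
  x <- seq(t_min, t_max, by = pitch)
  with_seed_maybe(seed, function() {
    tibble(series = "melt", x = x,
           y = melt_model(x, m_folded, b_folded, m_unfolded, b_unfolded,
                          tm_celsius, delta_h) + rnorm(length(x), sd = sigma))
  })
}

#' Simulate a turbidity trace
#'
#' Phase separation is modelled as a logistic rise of A395 to a plateau.
#' In `"inhibition"` mode the RNA is present from the start and scales the
#' plateau by `(1 - inhibitor_strength) * enhancement` (the enhancement
#' multiplier > 1 reproduces the low-concentration increase in droplet
#' number). In `"reversal"` mode the trace rises untreated, then from
#' `rna_add_time` the signal is multiplied by an exponential decay toward
#' the floor `1 - inhibitor_strength`, so `inhibitor_strength = 0` leaves
#' the post-addition trace statistically flat and `1` dissolves it fully.
#'
#' @param mode `"reversal"` or `"inhibition"`.
#' @param duration Trace length (min), 1-min cycles from 0.
#' @param plateau Untreated plateau absorbance.
#' @param rate Logistic rate (1/min).
#' @param t_mid Logistic midpoint (min).
#' @param rna_add_time RNA addition time for reversal mode (min).
#' @param inhibitor_strength In `[0, 1]`.
#' @param enhancement Multiplier for low-concentration enhancement.
#' @param decay_rate Post-addition decay rate (1/min).
#' @param sigma Gaussian noise sd (absorbance).
#' @param series,role Metadata columns for the output.
#' @param seed Integer seed.
#' @return Trace tibble (`series`, `time`, `a395`, `role`,
#'   `rna_add_time`).
#' @export
simulate_turbidity <- function(mode = c("reversal", "inhibition"),
                               duration = 180, plateau = 1, rate = 0.15,
                               t_mid = 30, rna_add_time = 60,
                               inhibitor_strength = 0, enhancement = 1,
                               decay_rate = 0.05, sigma = 0.01,
                               series = "trace", role = "sample",
                               seed = NULL) {
  mode <- match.arg(mode)
  if (inhibitor_strength < 0 || inhibitor_strength > 1) {
    abort("inhibitor_strength must lie in [0, 1]")
  }
  if (sigma < 0) abort("sigma must be >= 0")
  time <- seq(0, duration, by = 1)
  base <- plateau / (1 + exp(-rate * (time - t_mid)))
  y <- if (mode == "inhibition") {
    base * enhancement * (1 - inhibitor_strength)
  } else {
    scale <- rep(1, length(time))
    post <- time >= rna_add_time
    floor_lvl <- 1 - inhibitor_strength
    scale[post] <- floor_lvl + (1 - floor_lvl) *
      exp(-decay_rate * (time[post] - rna_add_time))
    base * enhancement * scale
  }
  with_seed_maybe(seed, function() {
    tibble(series = series, time = time,
           a395 = y + rnorm(length(time), sd = sigma),
           role = role,
           rna_add_time = if (mode == "reversal") rna_add_time else NA_real_)
  })
}

place_disks <- function(n, shape, radius_range, margin = 1,
                        forbidden = NULL, max_tries = 1000) {
  centers <- matrix(numeric(0), ncol = 3)
  tries <- 0
  while (nrow(centers) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      abort("cannot place the requested disks without overlap")
    }
    r <- if (radius_range[1] == radius_range[2]) radius_range[1] else {
      runif(1, radius_range[1], radius_range[2])
    }
    row <- runif(1, r + margin + 1, shape[1] - r - margin)
    col <- runif(1, r + margin + 1, shape[2] - r - margin)
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - row)^2 + (centers[, 2] - col)^2)
      if (any(d < centers[, 3] + r + 2 * margin)) next
    }
    if (!is.null(forbidden) &&
        forbidden[round(row), round(col)]) next
    centers <- rbind(centers, c(row, col, r))
  }
  centers
}

disk_mask <- function(shape, row, col, r) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rr - row)^2 + (cc - col)^2 <= r^2
}

#' Simulate a droplet image with known ground truth
#'
#' Plants non-overlapping bright disks on a flat background plus Gaussian
#' noise.
#'
#' @param shape Image dimensions in px (default `c(256, 256)`).
#' @param n_droplets Number of planted droplets (default 7).
#' @param radius_range Disk radius range in px (default `c(4, 10)`,
#'   >= 2 px).
#' @param intensity_inside,intensity_background Disk / background mean
#'   intensities (default 200 / 100).
#' @param noise_sd Gaussian noise sd (default 2).
#' @param seed Integer seed.
#' @return List with `image` (matrix), `labels` (planted label matrix) and
#'   `truth` (tibble: `label`, `row`, `col`, `radius`, `area`).
#' @export
simulate_droplet_image <- function(shape = c(256, 256), n_droplets = 7,
                                   radius_range = c(4, 10),
                                   intensity_inside = 200,
                                   intensity_background = 100,
                                   noise_sd = 2, seed = NULL) {
  if (any(radius_range < 2)) abort("radii must be >= 2 px")
  if (intensity_inside <= 0 || intensity_background <= 0) {
    abort("intensities must be > 0")
  }
  with_seed_maybe(seed, function() {
    img <- matrix(intensity_background, shape[1], shape[2])
    labels <- matrix(0L, shape[1], shape[2])
    truth <- tibble(label = integer(), row = double(), col = double(),
                    radius = double(), area = double())
    if (n_droplets > 0) {
      centers <- place_disks(n_droplets, shape, radius_range)
      for (i in seq_len(nrow(centers))) {
        m <- disk_mask(shape, centers[i, 1], centers[i, 2], centers[i, 3])
        img[m] <- intensity_inside
        labels[m] <- i
        truth <- dplyr::bind_rows(truth, tibble(
          label = i, row = centers[i, 1], col = centers[i, 2],
          radius = centers[i, 3], area = sum(m)))
      }
    }
    img <- img + matrix(rnorm(length(img), sd = noise_sd), shape[1], shape[2])
    list(image = img, labels = labels, truth = truth)
  })
}

#' Simulate a two-channel cell image for colocalization analysis
#'
#' Builds a DAPI-like nuclei channel (large disks) and two foci channels
#' sharing a controlled fraction `shared_fraction` of cytoplasmic foci
#' positions; each channel also carries nuclear foci (which the
#' cytoplasmic masking must remove). Ground-truth masks are returned.
#'
#' @param shape Image dimensions (default `c(256, 256)`).
#' @param n_nuclei Number of nuclei (default 3).
#' @param nucleus_radius Nucleus radius in px (default 24).
#' @param n_foci Cytoplasmic foci per channel (default 30).
#' @param focus_radius Focus radius in px (default 2).
#' @param shared_fraction Fraction of foci at positions shared by both
#'   channels, in `[0, 1]`.
#' @param n_nuclear_foci Foci planted inside nuclei per channel (default 5).
#' @param intensity_nucleus,intensity_focus,background Channel intensities.
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer seed.
#' @return List with `nuclei`, `channel_a`, `channel_b` (matrices) and
#'   `truth` (list: `mask_a`, `mask_b` cytoplasmic-foci masks,
#'   `nuclei_mask`, `shared_fraction`).
#' @export
simulate_cell_image <- function(shape = c(256, 256), n_nuclei = 3,
                                nucleus_radius = 24, n_foci = 30,
                                focus_radius = 2, shared_fraction = 0.5,
                                n_nuclear_foci = 5,
                                intensity_nucleus = 150,
                                intensity_focus = 200, background = 50,
                                noise_sd = 2, seed = NULL) {
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("shared_fraction must lie in [0, 1]")
  }
  if (focus_radius < 2) abort("radii must be >= 2 px")
  with_seed_maybe(seed, function() {
    nuclei_mask <- matrix(FALSE, shape[1], shape[2])
    nuc_centers <- place_disks(n_nuclei, shape,
                               c(nucleus_radius, nucleus_radius), margin = 3)
    for (i in seq_len(nrow(nuc_centers))) {
      nuclei_mask <- nuclei_mask |
        disk_mask(shape, nuc_centers[i, 1], nuc_centers[i, 2],
                  nuc_centers[i, 3])
    }

    n_shared <- round(shared_fraction * n_foci)
    n_unique <- n_foci - n_shared
    total <- n_shared + 2 * n_unique
    cyto_centers <- place_disks(total, shape,
                                c(focus_radius, focus_radius),
                                forbidden = nuclei_mask)
    shared_idx <- seq_len(n_shared)
    a_idx <- c(shared_idx, n_shared + seq_len(n_unique))
    b_idx <- c(shared_idx, n_shared + n_unique + seq_len(n_unique))
    # per-focus brightness; a shared focus keeps one draw in both channels,
    # so colocalized foci carry correlated (not just coincident) signal
    focus_int <- intensity_focus * runif(total, 0.5, 1.5)

    foci_mask <- function(idx) {
      m <- matrix(FALSE, shape[1], shape[2])
      for (i in idx) {
        m <- m | disk_mask(shape, cyto_centers[i, 1], cyto_centers[i, 2],
                           cyto_centers[i, 3])
      }
      m
    }
    mask_a <- foci_mask(a_idx)
    mask_b <- foci_mask(b_idx)

    # plant nuclear foci well inside the nucleus (not at the rim), as
    # nuclear speckles are; the rim is the analysis' peri-nuclear zone
    interior <- EBImage::erode(
      EBImage::Image(nuclei_mask * 1),
      EBImage::makeBrush(2 * (focus_radius + 8) + 1, shape = "disc")) > 0
    nuclear_foci <- function() {
      out <- list()
      if (n_nuclear_foci == 0 || !any(interior)) return(out)
      inside <- which(interior)
      pick <- sample(inside, min(n_nuclear_foci, length(inside)))
      lapply(pick, function(px) {
        c((px - 1) %% shape[1] + 1, (px - 1) %/% shape[1] + 1)
      })
    }
    nuc_foci_a <- nuclear_foci()
    nuc_foci_b <- nuclear_foci()

    channel <- function(idx, nuc_foci) {
      img <- matrix(background, shape[1], shape[2])
      for (i in idx) {
        m <- disk_mask(shape, cyto_centers[i, 1], cyto_centers[i, 2],
                       cyto_centers[i, 3])
        img[m] <- focus_int[i]
      }
      for (ctr in nuc_foci) {
        m <- disk_mask(shape, ctr[1], ctr[2], focus_radius)
        img[m] <- intensity_focus * runif(1, 0.5, 1.5)
      }
      img + matrix(rnorm(length(img), sd = noise_sd), shape[1], shape[2])
    }
    nuclei_img <- matrix(background, shape[1], shape[2])
    nuclei_img[nuclei_mask] <- intensity_nucleus
    nuclei_img <- nuclei_img +
      matrix(rnorm(length(nuclei_img), sd = noise_sd), shape[1], shape[2])

    list(nuclei = nuclei_img,
         channel_a = channel(a_idx, nuc_foci_a),
         channel_b = channel(b_idx, nuc_foci_b),
         truth = list(mask_a = mask_a, mask_b = mask_b,
                      nuclei_mask = nuclei_mask,
                      shared_fraction = shared_fraction))
  })
}

#' Deterministic RNA panel of rG4-positive and rG4-negative sequences
#'
#' A fixed panel for exercising the motif scanner: the archetypal
#' FUS-binding repeat `(GGU)8`, the C9orf72 hexanucleotide repeat
#' `(GGGGCC)4`, a TERRA-like telomeric repeat `(UUAGGG)4`, a poly-A
#' negative control, and G4-ablated controls in which the G-runs are
#' broken without changing length or base composition class.
#'
#' @param seed Unused; accepted for API symmetry with the other
#'   generators (the panel is fixed).
#' @return A tibble with columns `name`, `sequence`, `expected_rg4`.
#' @export
make_sequence_panel <- function(seed = NULL) {
  tibble(
    name = c("GGU8", "G4C2x4", "TERRA4", "polyA30",
             "GGU8_G4neg", "G4C2x4_G4neg"),
    sequence = c(strrep("GGU", 8),
                 strrep("GGGGCC", 4),
                 strrep("UUAGGG", 4),
                 strrep("A", 30),
                 strrep("GAU", 8),
                 strrep("GACGUC", 4)),
    expected_rg4 = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}
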