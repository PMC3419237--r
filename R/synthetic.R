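## Seeded synthetic-data generators emulating the study design: powder EPR
## spectra with known spin systems and spin counts, first-order radical
## decay series, six-group qPCR plates normalised to an exogenous standard,
## and protein families evolved along a known tree.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

.EXPOSURE_GROUPS <- c("normoxia", "hypoxia", "anoxia_1d", "anoxia_3d",
                      "anoxia_5d", "reoxygenation")

#' Default synthetic-study configuration
#'
#' Bundles the seeded recipes for all generators, pre-filled with the study
#' design: six exposure groups (normoxia control, hypoxia, 1/3/5 days of
#' anoxia, reoxygenation) at n = 8 fish per group, measured primer-pair
#' efficiencies per tissue, a 10-fold Ki67 induction in anoxic brain as the
#' planted effect, tyrosyl/mixed-valent EPR presets, and a two-clade guide
#' tree for protein-family simulation.
#'
#' @param seed master RNG seed.
#' @return Nested list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1) {
  eff <- default_efficiencies()
  fold <- matrix(1, nrow = length(unique(eff$gene)),
                 ncol = length(.EXPOSURE_GROUPS),
                 dimnames = list(unique(eff$gene), .EXPOSURE_GROUPS))
  fold["Ki67", c("anoxia_1d", "anoxia_3d", "anoxia_5d")] <- 10
  structure(list(
    seed = seed,
    epr = list(preset = "carp_p53R2ii", frequency_GHz = 285,
               spin_concentration_uM = 200, noise_sd = 0.02),
    decay = list(k_per_hour = 0.01546, I0 = 1,
                 times_h = c(0, 24, 25), noise_sd = 0.005),
    qpcr = list(groups = .EXPOSURE_GROUPS, n_per_group = 8,
                tissues = c("brain", "heart"),
                efficiencies = eff, fold_changes = fold,
                base_cp = 26, cp_noise_sd = 0.1, bio_sd_log = 0.25,
                normalizer = "mw2060"),
    phylo = list(
      tree = "((A:0.1,B:0.1,(C:0.1,D:0.1):0.1):0.3,(E:0.1,F:0.1,(G:0.1,H:0.1):0.1):0.3);",
      seq_length = 300, rate = 1)),
    class = "scenario_config")
}

#' Measured primer-pair efficiencies per tissue
#'
#' The per-gene, per-tissue mean amplification efficiencies used for
#' relative quantification (fold per cycle), including the external
#' standard mw2060.
#'
#' @return Data frame with columns `gene`, `tissue`, `E`.
#' @export
default_efficiencies <- function() {
  b <- c(R1i = 1.72, R1ii = 1.79, R2i = 1.86, R2ii = 1.87, p53R2i = 1.84,
         p53R2ii = 1.88, PCNA = 1.83, BDNF = 1.87, Ki67 = 1.78, mw2060 = 1.82)
  h <- c(R1i = 1.83, R1ii = 1.86, R2i = 1.89, R2ii = 1.90, p53R2i = 1.90,
         p53R2ii = 1.90, PCNA = 1.89, BDNF = 1.87, Ki67 = 1.83, mw2060 = 1.89)
  rbind(
    data.frame(gene = names(b), tissue = "brain", E = unname(b)),
    data.frame(gene = names(h), tissue = "heart", E = unname(h)))
}

#' Synthetic powder EPR spectrum with known ground truth
#'
#' Simulates the preset spin system at the requested frequency, rescales
#' the intensity so that the double integral equals the spin concentration
#' (one arbitrary unit of double-integrated intensity per micromolar), and
#' adds Gaussian noise proportional to the maximum amplitude. Reproducible
#' for a fixed seed; `noise_sd = 0` returns the pure simulation.
#'
#' @param preset preset name (see [preset_spin_system()]).
#' @param frequency_GHz microwave frequency, GHz.
#' @param spin_concentration_uM true spin concentration, micromolar.
#' @param noise_sd additive Gaussian noise, as a fraction of the maximum
#'   amplitude; must be < 0.5 (larger is an unusable SNR).
#' @param seed RNG seed.
#' @param n_points,orientations simulation grid, passed to
#'   [powder_spectrum()].
#' @param field_range optional field window, mT.
#' @return List with `spectrum` (an [epr_spectrum()]) and `truth`
#'   (preset name, the generating `spin_system`, spin concentration,
#'   noise level, seed).
#' @export
make_epr_dataset <- function(preset, frequency_GHz,
                             spin_concentration_uM = 200,
                             noise_sd = 0, seed = 1,
                             n_points = 4096, orientations = 2000,
                             field_range = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (noise_sd >= 0.5) stop("noise_sd >= 0.5 gives an unusable SNR; refused")
  sys <- preset_spin_system(preset)
  sp <- powder_spectrum(sys, frequency_GHz, field_range = field_range,
                        n_points = n_points, orientations = orientations)
  di <- double_integral(sp, baseline = "none")
  sp$intensity <- sp$intensity * spin_concentration_uM / di
  if (noise_sd > 0) {
    amp <- max(abs(sp$intensity))
    sp$intensity <- sp$intensity +
      .with_seed(seed, stats::rnorm(length(sp$intensity), sd = noise_sd * amp))
  }
  sp$meta$spin_concentration_uM <- spin_concentration_uM
  list(spectrum = sp,
       truth = list(preset = preset, system = sys,
                    spin_concentration_uM = spin_concentration_uM,
                    noise_sd = noise_sd, seed = seed))
}

#' Synthetic radical-decay time series
#'
#' First-order decay `I(t) = I0 exp(-k t)` plus Gaussian noise, sampled by
#' default at the stability-assay design points: the t = 0 control, 24 h of
#' anoxic incubation, and one further hour (25 h) under normoxia.
#'
#' @param k_per_hour true decay constant (>= 0), per hour.
#' @param I0 initial intensity.
#' @param times_h sampling times, hours (non-negative).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed RNG seed.
#' @return List with `series` (data frame `time_h`, `intensity`) and
#'   `truth` (`k_per_hour`, `t_half_h`, `I0`, `seed`).
#' @export
make_decay_series <- function(k_per_hour, I0 = 1, times_h = c(0, 24, 25),
                              noise_sd = 0, seed = 1) {
  if (k_per_hour < 0) stop("k_per_hour must be non-negative")
  if (any(times_h < 0)) stop("negative times")
  y <- I0 * exp(-k_per_hour * times_h)
  if (noise_sd > 0)
    y <- y + .with_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  list(series = data.frame(time_h = times_h, intensity = y),
       truth = list(k_per_hour = k_per_hour,
                    t_half_h = if (k_per_hour > 0) log(2) / k_per_hour else Inf,
                    I0 = I0, seed = seed))
}

#' Synthetic logistic amplification curve
#'
#' Four-parameter logistic plus flat baseline whose exponential phase grows
#' by a factor `E` per cycle; the curve's second-derivative-maximum Cp has
#' the closed form `c0 - log(2 + sqrt(3)) / log(E)`, so a target Cp can be
#' planted exactly.
#'
#' @param E amplification efficiency in (1, 2].
#' @param cp target second-derivative-maximum Cp.
#' @param cycles number of cycles (default 42).
#' @param plateau,baseline fluorescence scale parameters.
#' @param noise_sd additive Gaussian noise SD (fluorescence units).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return Data frame with columns `cycle`, `fluorescence`.
#' @export
simulate_amplification_curve <- function(E, cp, cycles = 42, plateau = 10,
                                         baseline = 0.05, noise_sd = 0,
                                         seed = 1) {
  if (E <= 1 || E > 2) stop("E must lie in (1, 2]")
  c0 <- cp + log(2 + sqrt(3)) / log(E)
  cyc <- seq_len(cycles)
  y <- baseline + plateau / (1 + exp(-log(E) * (cyc - c0)))
  if (noise_sd > 0)
    y <- y + .with_seed(seed, stats::rnorm(cycles, sd = noise_sd))
  data.frame(cycle = cyc, fluorescence = pmax(y, 0))
}

#' Synthetic qPCR plate with planted fold-changes
#'
#' Generates a duplicate-reaction Cp table over the six exposure groups.
#' Per-sample target abundance is the group fold-change times lognormal
#' biological variation; Cp values encode abundance through the assigned
#' efficiency (`dCp = -log_E(fold)`), and the external standard is spiked
#' at a fixed amount (fold 1, no biological variation, Cp = `base_cp`) in
#' every sample. Target base Cp values are set so that a fold-change of 1
#' corresponds to a relative level of exactly 1
#' (`Cp_base = base_cp * log(E_std) / log(E_tar)`), making the truth
#' manifest directly comparable to [qpcr_relative_levels()] output.
#' Duplicates are jittered with technical Cp noise.
#'
#' @param cfg a [scenario_config()]; its `qpcr` section supplies groups,
#'   group sizes, tissues, efficiencies, fold-change matrix (genes x
#'   groups), base Cp, technical and biological noise, and the normaliser
#'   gene name.
#' @param seed RNG seed (default: the config's master seed).
#' @return List with `cp_table` (data frame `sample_id`, `group`, `tissue`,
#'   `gene`, `cp1`, `cp2`) and `truth` (fold-change matrix and noise
#'   parameters).
#' @export
make_qpcr_plate <- function(cfg = scenario_config(), seed = cfg$seed) {
  q <- cfg$qpcr
  genes <- rownames(q$fold_changes)
  if (!q$normalizer %in% genes)
    stop("normalizer gene '", q$normalizer, "' missing from the fold-change matrix")
  if (any(q$fold_changes[q$normalizer, ] != 1))
    stop("the external standard must have fold-change 1 in every group")
  if (any(q$fold_changes <= 0)) stop("fold-changes must be positive")
  if (any(q$efficiencies$E <= 1 | q$efficiencies$E > 2))
    stop("efficiencies must lie in (1, 2]")
  if (q$n_per_group < 2 || q$n_per_group > 20)
    stop("n_per_group must lie in [2, 20]")
  ekey <- paste(q$efficiencies$gene, q$efficiencies$tissue, sep = "\r")
  rows <- .with_seed(seed, {
    out <- list()
    for (tissue in q$tissues) for (grp in q$groups) {
      for (s in seq_len(q$n_per_group)) {
        sid <- sprintf("%s_%s_%02d", tissue, grp, s)
        E_std <- q$efficiencies$E[match(paste(q$normalizer, tissue, sep = "\r"),
                                        ekey)]
        for (gene in genes) {
          E <- q$efficiencies$E[match(paste(gene, tissue, sep = "\r"), ekey)]
          if (is.na(E)) next  # gene not assayed in this tissue
          fold <- q$fold_changes[gene, grp]
          bio <- if (gene == q$normalizer) 1 else
            exp(stats::rnorm(1, sd = q$bio_sd_log))
          cp_true <- if (gene == q$normalizer) q$base_cp else
            (q$base_cp * log(E_std) - log(fold * bio)) / log(E)
          cps <- cp_true + stats::rnorm(2, sd = q$cp_noise_sd)
          out[[length(out) + 1L]] <- data.frame(
            sample_id = sid, group = grp, tissue = tissue, gene = gene,
            cp1 = cps[1], cp2 = cps[2], stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
  list(cp_table = rows,
       truth = list(fold_changes = q$fold_changes, base_cp = q$base_cp,
                    cp_noise_sd = q$cp_noise_sd, bio_sd_log = q$bio_sd_log,
                    seed = seed))
}

#' Simulate a protein family along a guide tree
#'
#' Independent-site substitutions under an equal-rates 20-state model (the
#' amino-acid analogue of Jukes-Cantor): along a branch of length `l`, each
#' site changes with probability `(19/20) (1 - exp(-(20/19) rate l))` and
#' then draws uniformly among the 19 other residues. No indels, so the
#' sequences are already aligned. Deliberately non-empirical: sufficient
#' for topology-recovery experiments, not for simulating real proteins.
#'
#' @param tree guide tree: `ape::phylo` object or Newick string.
#' @param seq_length number of sites (> 0).
#' @param rate expected substitutions per site per unit branch length (> 0).
#' @param seed RNG seed.
#' @return List with `alignment` (character matrix, taxa x sites) and
#'   `tree` (the guide `phylo`).
#' @export
simulate_protein_family <- function(tree, seq_length = 300, rate = 1,
                                    seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (seq_length < 1L) stop("seq_length must be positive")
  if (rate <= 0) stop("rate must be positive")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  .with_seed(seed, {
    seqs <- vector("list", nnode)
    seqs[[root]] <- sample(aa, seq_length, replace = TRUE)
    ## preorder edge walk so parents are simulated before children
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      len <- if (is.null(ord$edge.length)) 0 else ord$edge.length[e]
      p_sub <- (19 / 20) * (1 - exp(-(20 / 19) * rate * len))
      s <- seqs[[parent]]
      hit <- which(stats::runif(seq_length) < p_sub)
      if (length(hit)) {
        for (i in hit) s[i] <- sample(setdiff(aa, s[i]), 1L)
      }
      seqs[[child]] <- s
    }
    m <- do.call(rbind, seqs[seq_len(ntip)])
    rownames(m) <- tree$tip.label
    list(alignment = m, tree = tree)
  })
}
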