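#' Simulation configuration for an in-silico restriction digest
#'
#' Defaults model MspI (cuts `C^CGG`) with the 180-2000 bp size selection used
#' for reduced-representation libraries.
#'
#' @param motif recognition sequence, default `"CCGG"`.
#' @param cut_offset bases after the fragment-side end at which the cut falls
#'   inside the motif (1 for `C^CGG`).
#' @param size_min,size_max retained fragment length bounds in bp.
#' @export
digest_config <- function(motif = "CCGG", cut_offset = 1L,
                          size_min = 180L, size_max = 2000L) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(motif))
    stop("cut_offset must lie within the motif")
  if (size_min <= 0 || size_min > size_max)
    stop("need 0 < size_min <= size_max")
  structure(list(motif = motif, cut_offset = cut_offset,
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max)),
            class = "digest_config")
}

#' Generate a synthetic reference genome with planted CpGs and capture probes
#'
#' Builds chromosomes whose only CG dinucleotides are the planted ones, so the
#' returned CpG list is exactly the set of CG occurrences. Probes (default
#' 120 bp) are each anchored on a randomly chosen CpG, guaranteeing every
#' probe overlaps at least one CpG.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp (>= 1000).
#' @param cpg_rate target CpG density per bp, in `[0, 0.2]`.
#' @param probes_per_chrom probes placed on each chromosome.
#' @param probe_length probe length in bp.
#' @param seed RNG seed; outputs are byte-identical for a fixed seed.
#'
#' @return list with `sequences` (named [Biostrings::DNAStringSet]),
#'   `cpg_sites` (data.frame `chrom`, `pos0`), `probes`
#'   ([genomic_intervals()]), `chrom_lengths` (named integer).
#' @export
gen_reference <- function(n_chroms = 2, chrom_length = 1e5, cpg_rate = 0.02,
                          probes_per_chrom = 40, probe_length = 120L,
                          seed = 1) {
  if (cpg_rate < 0 || cpg_rate > 0.2) stop("cpg_rate must be in [0, 0.2]")
  if (chrom_length < 1000) stop("chrom_length must be >= 1000")
  set.seed(seed)
  L <- as.integer(chrom_length)
  chroms <- paste0("chr", seq_len(n_chroms))
  seqs <- character(n_chroms)
  site_list <- vector("list", n_chroms)
  probe_list <- vector("list", n_chroms)
  for (ci in seq_len(n_chroms)) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # break accidental CG dinucleotides; replacement with A cannot create new ones
    cg <- which(s[-L] == "C" & s[-1] == "G")
    if (length(cg) > 0) s[cg + 1L] <- "A"
    pos <- integer(0)
    if (cpg_rate > 0) {
      cand <- which(stats::runif(L - 1L) < cpg_rate)
      if (length(cand) > 0) {
        keep <- cand[1]
        for (p in cand[-1]) if (p - keep[length(keep)] >= 2L) keep <- c(keep, p)
        pos <- keep
        s[pos] <- "C"
        s[pos + 1L] <- "G"
      }
    }
    seqs[ci] <- paste(s, collapse = "")
    found <- gregexpr("CG", seqs[ci], fixed = TRUE)[[1]]
    found <- if (found[1] == -1) integer(0) else as.integer(found) - 1L
    site_list[[ci]] <- data.frame(chrom = rep(chroms[ci], length(found)),
                                  pos0 = found, stringsAsFactors = FALSE)
    if (length(found) > 0 && probes_per_chrom > 0) {
      anchors <- sort(sample(found, min(probes_per_chrom, length(found))))
      offs <- sample.int(probe_length - 1L, length(anchors), replace = TRUE) - 1L
      start <- pmin(pmax(anchors - offs, 0L), L - probe_length)
      probe_list[[ci]] <- genomic_intervals(
        chroms[ci], start, start + probe_length,
        name = sprintf("%s_probe%03d", chroms[ci], seq_along(anchors)))
    } else probe_list[[ci]] <- empty_intervals()
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- chroms
  probes <- do.call(rbind, probe_list)
  class(probes) <- c("genomic_intervals", "data.frame")
  list(sequences = dna,
       cpg_sites = do.call(rbind, site_list),
       probes = probes,
       chrom_lengths = stats::setNames(rep(L, n_chroms), chroms))
}

#' Simulate per-sample methylomes with known ground truth
#'
#' Per site, a baseline methylation proportion is drawn from a two-component
#' beta mixture (hypo/hyper modes, giving the bimodal genome-wide profile of
#' mammalian methylomes). Effect sites carry a group-1 shift of exactly
#' `delta`. Per cell (site x sample), coverage is negative-binomial and the
#' methylated count is binomial with success probability
#' `pi * (1 - inv_error) + (1 - pi) * conv_error`, modelling incomplete
#' enzymatic conversion. CHH-context records with methylation probability
#' `conv_error` are emitted alongside, so conversion QC can recover the error
#' rate.
#'
#' @param ref reference as returned by [gen_reference()] (or any list with a
#'   `cpg_sites` data.frame).
#' @param n_per_group integer vector of group sizes (length 2).
#' @param delta group-1 methylation shift at effect sites (0-1).
#' @param n_effect number of effect sites to plant (chosen among sites where
#'   `pi + delta <= 1`).
#' @param effect_sites explicit site indices to plant effects at; overrides
#'   `n_effect`. An explicit site with `pi + delta > 1` is an error.
#' @param mu_cov negative-binomial mean coverage per cell (study-like: 20).
#' @param disp negative-binomial size (dispersion) parameter.
#' @param conv_error probability an unmethylated C reads methylated (in
#'   `[0, 0.05]`).
#' @param inv_error probability a methylated C reads unmethylated (default 0).
#' @param mix_w,a_low,b_low,a_high,b_high beta-mixture baseline parameters.
#' @param n_chh CHH-context cytosines emitted per sample.
#' @param split_strands emit CpG counts split across both strands of the
#'   dinucleotide (exercises strand collapsing) instead of plus-strand only.
#' @param seed RNG seed.
#'
#' @return list: `reports` (named list of cytosine-report data.frames, one per
#'   sample), `M`, `U` (sites x samples count matrices), `meta` (sample,
#'   group), `truth` (per-site `pi_group0`, `pi_group1`, `effect` flag),
#'   `sites`.
#' @export
gen_methylome <- function(ref, n_per_group = c(8, 8), delta = 0,
                          n_effect = 0, effect_sites = NULL,
                          mu_cov = 20, disp = 2,
                          conv_error = 0.005, inv_error = 0,
                          mix_w = 0.5, a_low = 1, b_low = 10,
                          a_high = 10, b_high = 1,
                          n_chh = 500, split_strands = FALSE, seed = 1) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 1))
  if (conv_error < 0 || conv_error > 0.05)
    stop("conv_error must be in [0, 0.05]")
  set.seed(seed)
  sites <- ref$cpg_sites
  ns <- nrow(sites)
  if (ns == 0) stop("reference has no CpG sites")
  low <- stats::runif(ns) < mix_w
  pi0 <- ifelse(low, stats::rbeta(ns, a_low, b_low),
                stats::rbeta(ns, a_high, b_high))
  eff <- rep(FALSE, ns)
  if (!is.null(effect_sites)) {
    eff[effect_sites] <- TRUE
    if (any(pi0[eff] + delta > 1))
      stop("pi + delta > 1 at an effect site")
  } else if (n_effect > 0) {
    eligible <- which(pi0 + delta <= 1)
    if (length(eligible) < n_effect)
      stop("not enough sites with pi + delta <= 1 to plant effects")
    eff[sample(eligible, n_effect)] <- TRUE
  }
  pi1 <- pi0
  pi1[eff] <- pi0[eff] + delta
  n_tot <- sum(n_per_group)
  group <- rep(c(0L, 1L), n_per_group)
  samples <- sprintf("s%02d", seq_len(n_tot))
  M <- matrix(0L, ns, n_tot, dimnames = list(NULL, samples))
  U <- matrix(0L, ns, n_tot, dimnames = list(NULL, samples))
  reports <- vector("list", n_tot)
  names(reports) <- samples
  chrom1 <- names(ref$chrom_lengths)[1] %||% sites$chrom[1]
  chh_pool <- setdiff(seq_len(min(ref$chrom_lengths[1] %||% 1e6, 1e6)) - 1L,
                      c(sites$pos0, sites$pos0 + 1L))
  for (j in seq_len(n_tot)) {
    pij <- if (group[j] == 0L) pi0 else pi1
    p_obs <- pij * (1 - inv_error) + (1 - pij) * conv_error
    cov <- stats::rnbinom(ns, mu = mu_cov, size = disp)
    m <- stats::rbinom(ns, cov, p_obs)
    M[, j] <- m
    U[, j] <- cov - m
    if (split_strands) {
      c_plus <- stats::rbinom(ns, cov, 0.5)
      m_plus <- rhyper_safe(m, cov - m, c_plus)
      rep_cpg <- data.frame(
        chrom = rep(sites$chrom, 2),
        pos1 = c(sites$pos0 + 1L, sites$pos0 + 2L),
        strand = rep(c("+", "-"), each = ns),
        M = c(m_plus, m - m_plus),
        U = c(c_plus - m_plus, (cov - c_plus) - (m - m_plus)),
        context = "CpG", stringsAsFactors = FALSE)
    } else {
      rep_cpg <- data.frame(chrom = sites$chrom, pos1 = sites$pos0 + 1L,
                            strand = "+", M = m, U = cov - m,
                            context = "CpG", stringsAsFactors = FALSE)
    }
    if (n_chh > 0) {
      chh_pos <- sample(chh_pool, min(n_chh, length(chh_pool)))
      chh_cov <- stats::rnbinom(length(chh_pos), mu = mu_cov, size = disp)
      chh_m <- stats::rbinom(length(chh_pos), chh_cov, conv_error)
      rep_chh <- data.frame(chrom = chrom1, pos1 = chh_pos + 1L,
                            strand = "+", M = chh_m, U = chh_cov - chh_m,
                            context = "CHH", stringsAsFactors = FALSE)
      reports[[j]] <- rbind(rep_cpg, rep_chh)
    } else reports[[j]] <- rep_cpg
  }
  list(reports = reports, M = M, U = U,
       meta = data.frame(sample = samples, group = group,
                         stringsAsFactors = FALSE),
       truth = data.frame(chrom = sites$chrom, pos0 = sites$pos0,
                          pi_group0 = pi0, pi_group1 = pi1, effect = eff,
                          stringsAsFactors = FALSE),
       sites = sites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hypergeometric split of m methylated among a subsample of k reads out of
# m + u; vectorized and safe for k = 0.
rhyper_safe <- function(m, u, k) {
  out <- integer(length(m))
  pos <- k > 0
  if (any(pos)) out[pos] <- stats::rhyper(sum(pos), m[pos], u[pos], k[pos])
  out
}

#' Simulate microarray beta values with an intensity offset
#'
#' Emulates the array's beta computation: beta = S_m / (S_m + S_u + offset),
#' with methylated/unmethylated intensities proportional to the true
#' methylation level plus Gaussian noise (truncated at 0). With a positive
#' offset, beta values of 1 are impossible by construction.
#'
#' @param m matrix or vector of true methylation levels in `[0, 1]`.
#' @param alpha_off intensity offset (>= 0), default 100.
#' @param noise_sd Gaussian intensity noise SD (same units as intensity).
#' @param total_intensity total signal per locus, default 1000.
#' @param seed RNG seed.
#' @return object shaped like `m` with simulated beta values.
#' @export
gen_array_betas <- function(m, alpha_off = 100, noise_sd = 0,
                            total_intensity = 1000, seed = 1) {
  if (alpha_off < 0) stop("alpha_off must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  n <- length(m)
  sm <- pmax(0, as.numeric(m) * total_intensity + stats::rnorm(n, 0, noise_sd))
  su <- pmax(0, (1 - as.numeric(m)) * total_intensity + stats::rnorm(n, 0, noise_sd))
  beta <- ifelse(sm + su + alpha_off > 0, sm / (sm + su + alpha_off), NA_real_)
  if (is.matrix(m)) matrix(beta, nrow(m), ncol(m), dimnames = dimnames(m))
  else beta
}

#' Simulate sequenced fragments as an on/off-target mixture
#'
#' With probability `on_target_prob` a fragment is placed within `flank` bp of
#' a uniformly chosen probe; otherwise uniformly on the genome. The default
#' mixing proportion 0.785 reflects the on-target read fraction typical of a
#' well-performing hybridization capture.
#'
#' @param probes probe intervals (non-empty).
#' @param n_fragments number of fragments.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param on_target_prob probability of on-target placement.
#' @param flank on-target tolerance in bp (default 200).
#' @param len_mean,len_sd fragment length distribution (normal, floored at 50).
#' @param seed RNG seed.
#' @return fragment intervals ([genomic_intervals()]).
#' @export
gen_fragments <- function(probes, n_fragments, chrom_lengths,
                          on_target_prob = 0.785, flank = 200L,
                          len_mean = 160, len_sd = 30, seed = 1) {
  probes <- as_intervals(probes)
  if (nrow(probes) == 0) stop("probe set is empty")
  if (on_target_prob < 0 || on_target_prob > 1)
    stop("on_target_prob must be in [0, 1]")
  if (n_fragments == 0) return(empty_intervals())
  set.seed(seed)
  len <- pmax(50L, as.integer(round(stats::rnorm(n_fragments, len_mean, len_sd))))
  on <- stats::runif(n_fragments) < on_target_prob
  chrom <- character(n_fragments)
  start <- integer(n_fragments)
  if (any(on)) {
    idx <- sample.int(nrow(probes), sum(on), replace = TRUE)
    ps <- probes$start[idx]; pe <- probes$end[idx]
    chrom[on] <- probes$chrom[idx]
    lo <- ps - flank - len[on]
    hi <- pe + flank
    s <- lo + floor(stats::runif(sum(on)) * (hi - lo + 1))
    cl <- chrom_lengths[chrom[on]]
    start[on] <- pmin(pmax(s, 0L), cl - len[on])
  }
  if (any(!on)) {
    ci <- sample(names(chrom_lengths), sum(!on), replace = TRUE)
    chrom[!on] <- ci
    start[!on] <- floor(stats::runif(sum(!on)) * (chrom_lengths[ci] - len[!on]))
  }
  genomic_intervals(chrom, start, start + len,
                    name = sprintf("frag%06d", seq_len(n_fragments)))
}

#' In-silico restriction digest with size selection
#'
#' Cuts the sequence at every occurrence of the recognition motif (offset
#' `cut_offset` into the motif, MspI-style `C^CGG` by default), yielding
#' fragments that partition `[0, len)`. Fragments within the configured size
#' bounds are retained, and all CpGs whose plus-strand C lies on a retained
#' fragment are reported as covered — the reduced-representation site
#' selection.
#'
#' @param sequence a character string, [Biostrings::DNAString], or a single
#'   element of a DNAStringSet.
#' @param config a [digest_config()].
#' @param chrom chromosome name for the returned intervals.
#' @return list: `fragments` (all fragments), `retained` (size-selected),
#'   `covered_cpgs` (data.frame `chrom`, `pos0`).
#' @export
msp1_digest <- function(sequence, config = digest_config(), chrom = "seq") {
  s <- as.character(sequence)
  if (length(s) != 1) stop("one sequence at a time")
  len <- nchar(s)
  hits <- gregexpr(config$motif, s, fixed = TRUE)[[1]]
  starts0 <- if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
  cuts <- sort(unique(starts0 + config$cut_offset))
  cuts <- cuts[cuts > 0 & cuts < len]
  bounds <- c(0L, cuts, len)
  frags <- genomic_intervals(chrom, bounds[-length(bounds)], bounds[-1],
                             name = sprintf("dig%05d", seq_len(length(bounds) - 1)))
  w <- frags$end - frags$start
  keep <- w >= config$size_min & w <= config$size_max
  retained <- frags[keep, , drop = FALSE]
  class(retained) <- c("genomic_intervals", "data.frame")
  cg <- gregexpr("CG", s, fixed = TRUE)[[1]]
  cg <- if (cg[1] == -1) integer(0) else as.integer(cg) - 1L
  covered <- if (nrow(retained) > 0 && length(cg) > 0) {
    inside <- vapply(cg, function(p)
      any(p >= retained$start & p < retained$end), logical(1))
    cg[inside]
  } else integer(0)
  list(fragments = frags, retained = retained,
       covered_cpgs = data.frame(chrom = rep(chrom, length(covered)),
                                 pos0 = covered, stringsAsFactors = FALSE))
}
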