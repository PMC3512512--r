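#' Describe one aberration event for the simulator
#'
#' @param fraction fraction of the genome's SNP markers covered by the
#'   event (the region is contiguous within one chromosome and clipped to
#'   the chromosome if necessary).
#' @param type one of \code{"deletion"} (one allele lost),
#'   \code{"gain"} (one allele duplicated), \code{"loh"} (copy-neutral
#'   loss of heterozygosity), \code{"homozygous_deletion"} (both alleles
#'   lost), \code{"amplification"} (one allele gains two copies).
#' @param recurrence fraction of samples carrying the event; exactly
#'   \code{floor(recurrence * n_samples)} samples are affected.
#' @param location \code{"random"} (each affected sample gets its own
#'   location) or \code{"fixed"} (all affected samples share identical bp
#'   bounds, as in a recurrent aberration).
#' @return a list describing the event.
#' @export
aberration <- function(fraction,
                       type = c("deletion", "gain", "loh",
                                "homozygous_deletion", "amplification"),
                       recurrence = 1, location = c("random", "fixed")) {
  type <- match.arg(type)
  location <- match.arg(location)
  if (fraction < 0 || fraction > 1 || recurrence < 0 || recurrence > 1)
    stop("fraction and recurrence must lie in [0, 1]")
  list(fraction = fraction, type = type, recurrence = recurrence,
       location = location)
}

#' Default aberration landscape
#'
#' Two deletions, one gain and one copy-neutral LOH event per sample,
#' placed at random locations, covering about 20% of the genome - a
#' moderately rearranged tumor in which every locus still has a majority
#' of normal samples.
#'
#' @return list of \code{\link{aberration}} events.
#' @export
default_aberrations <- function() {
  list(aberration(0.06, "deletion"), aberration(0.06, "gain"),
       aberration(0.04, "loh"), aberration(0.04, "deletion"))
}

#' Simulation configuration
#'
#' Defines the synthetic SNP-array study: genome layout, germline genotype
#' model, somatic aberrations, tumor purity, hybridization batches and the
#' signal model. Signals are rendered as
#' \deqn{\theta = \varphi_j \, b_{batch(i),j} \, c \, e^{\varepsilon} +
#'       \delta \varphi_j,}
#' with a per-probe proportionality constant \eqn{\varphi_j} (log-normal,
#' sd \code{probe_log_sd}), a per-batch per-probe factor (log-normal, sd
#' \code{batch_log_sd}), effective allele copies
#' \eqn{c = purity \cdot tumor + (1 - purity) \cdot germline},
#' multiplicative log-normal noise (sd \code{noise_sd}) and a small
#' additive floor \eqn{\delta \varphi_j} (default \eqn{\delta = 0.05})
#' emulating cross-hybridization background so null alleles never give an
#' exactly-zero signal.
#'
#' The default minor-allele-frequency prior Beta(0.6, 1.6) yields an
#' expected Hardy-Weinberg heterozygosity of 2(E[p] - E[p^2]) = 0.2727,
#' matching the ~27% heterozygous SNPs per sample seen in HapMap-like
#' populations.
#'
#' @param n_samples number of samples.
#' @param n_chromosomes,snps_per_chr,cn_probes_per_chr,chr_length_bp
#'   genome layout (chromosomes are identical in size).
#' @param maf_beta shape parameters of the Beta MAF prior.
#' @param maf_fixed optional scalar overriding the prior with a constant
#'   MAF for every SNP.
#' @param aberrations list of \code{\link{aberration}} events.
#' @param purity tumor cell fraction in (0, 1], scalar or per sample.
#' @param n_batches,batch_log_sd hybridization batches and the log-sd of
#'   their per-probe multiplicative effects.
#' @param noise_sd log-sd of the per-signal multiplicative noise.
#' @param probe_log_sd log-sd of the per-probe proportionality constants.
#' @param signal_floor the floor coefficient \eqn{\delta}.
#' @param seed integer master seed.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_samples = 20L, n_chromosomes = 20L,
                       snps_per_chr = 1000L, cn_probes_per_chr = 50L,
                       chr_length_bp = 1e8, maf_beta = c(0.6, 1.6),
                       maf_fixed = NULL, aberrations = default_aberrations(),
                       purity = 1, n_batches = 1L, batch_log_sd = 0,
                       noise_sd = 0.05, probe_log_sd = 0.3,
                       signal_floor = 0.05, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chr = as.integer(snps_per_chr),
              cn_probes_per_chr = as.integer(cn_probes_per_chr),
              chr_length_bp = chr_length_bp, maf_beta = maf_beta,
              maf_fixed = maf_fixed, aberrations = aberrations,
              purity = purity, n_batches = as.integer(n_batches),
              batch_log_sd = batch_log_sd, noise_sd = noise_sd,
              probe_log_sd = probe_log_sd, signal_floor = signal_floor,
              seed = as.integer(seed))
  if (cfg$n_samples < 1L || cfg$n_chromosomes < 1L || cfg$snps_per_chr < 1L)
    stop("sample, chromosome and SNP counts must be >= 1")
  if (any(cfg$purity <= 0) || any(cfg$purity > 1))
    stop("purity must lie in (0, 1]")
  if (cfg$noise_sd < 0 || cfg$batch_log_sd < 0 || cfg$probe_log_sd < 0)
    stop("standard deviations must be >= 0")
  for (ab in cfg$aberrations)
    if (!all(c("fraction", "type", "recurrence", "location") %in% names(ab)))
      stop("aberrations must be built with aberration()")
  class(cfg) <- "sim_config"
  cfg
}

# genome layout: annotation plus marker bookkeeping
.sim_annotation <- function(config) {
  nc <- config$n_chromosomes
  js <- config$snps_per_chr
  jc <- config$cn_probes_per_chr
  chr_names <- sprintf("chr%02d", seq_len(nc))
  snp_pos <- round(config$chr_length_bp * seq_len(js) / (js + 1))
  cn_pos <- if (jc > 0) round(config$chr_length_bp * seq_len(jc) / (jc + 1)) + 7
            else integer(0)
  ann <- probe_annotation(
    probe_id = c(t(outer(chr_names, seq_len(js),
                         function(c, k) sprintf("SNP_%s_%04d", c, k))),
                 if (jc > 0) c(t(outer(chr_names, seq_len(jc),
                          function(c, k) sprintf("CN_%s_%04d", c, k))))),
    chromosome = c(rep(chr_names, each = js), rep(chr_names, each = jc)),
    position = c(rep(snp_pos, times = nc), rep(cn_pos, times = nc)),
    probe_class = c(rep("SNP", nc * js), rep("CN", nc * jc)))
  list(annotation = ann, chr_names = chr_names, snp_pos = snp_pos)
}

#' Simulate germline genotypes
#'
#' Draws a minor-allele frequency per SNP from the configured Beta prior
#' (or the fixed override) and Hardy-Weinberg genotypes per sample at that
#' frequency.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{germ_a}, \code{germ_b} (SNPs x samples integer
#'   allele copies, ordered chromosome-major as in the annotation) and
#'   \code{maf}.
#' @export
simulate_genotypes <- function(config) {
  old <- .derived_rng(config$seed)
  on.exit(.restore_rng(old))
  J <- config$n_chromosomes * config$snps_per_chr
  I <- config$n_samples
  maf <- if (!is.null(config$maf_fixed)) rep(config$maf_fixed, J)
         else stats::rbeta(J, config$maf_beta[1L], config$maf_beta[2L])
  nb <- matrix(stats::rbinom(J * I, 2L, rep(maf, I)), J, I)
  list(germ_a = 2L - nb, germ_b = nb, maf = maf)
}

#' Apply somatic aberrations to germline genotypes
#'
#' Lays the configured aberration events onto each sample's genome as
#' piecewise-constant allele-copy profiles. Deletions remove one allele
#' (a fair seeded coin picks which for heterozygotes), gains duplicate
#' one, LOH replaces AB with AA or BB keeping two copies, homozygous
#' deletions remove both, amplifications add two copies of one allele.
#' Fixed-location recurrent events share identical bp bounds across the
#' affected samples; random-location events are placed independently per
#' sample, avoiding overlap (overlapping fixed events are an error).
#'
#' @param genotypes output of \code{\link{simulate_genotypes}}.
#' @param config the same \code{\link{sim_config}}.
#' @return A ground-truth list: \code{cn_a}, \code{cn_b} (tumor allele
#'   copies per SNP), \code{cn_total} (total copies over all probes, CN
#'   probes included), \code{normal} (logical matrix over all probes: TRUE
#'   where the marker lies in no event region), \code{regions}
#'   (data.frame of applied events), plus the inherited germline fields.
#' @export
apply_aberrations <- function(genotypes, config) {
  old <- .derived_rng(config$seed + 1L)
  on.exit(.restore_rng(old))
  layout <- .sim_annotation(config)
  ann <- layout$annotation
  I <- config$n_samples
  J <- config$n_chromosomes * config$snps_per_chr
  cn_a <- genotypes$germ_a
  cn_b <- genotypes$germ_b
  total_cn <- matrix(2L, nrow(ann), I, dimnames = list(ann$probe_id, NULL))
  normal <- matrix(TRUE, nrow(ann), I, dimnames = list(ann$probe_id, NULL))
  is_snp <- ann$probe_class == "SNP"
  occupied <- vector("list", I)   # per sample: data.frame(chr, start, end)
  regions <- list()
  delta_total <- c(deletion = -1L, gain = 1L, loh = 0L,
                   homozygous_deletion = -2L, amplification = 2L)
  for (ab in config$aberrations) {
    len <- max(1L, min(round(ab$fraction * J), config$snps_per_chr))
    n_aff <- floor(ab$recurrence * I)
    if (n_aff == 0L) next
    affected <- if (n_aff == I) seq_len(I) else sort(sample.int(I, n_aff))
    if (ab$location == "fixed") {
      chr <- sample.int(config$n_chromosomes, 1L)
      start <- sample.int(config$snps_per_chr - len + 1L, 1L)
      loc <- list(chr = chr, start = start)
    }
    for (si in affected) {
      if (ab$location == "fixed") {
        chr <- loc$chr; start <- loc$start
        if (.overlaps(occupied[[si]], chr, start, start + len - 1L))
          stop("overlapping aberration regions in the event specification")
      } else {
        placed <- FALSE
        for (try in seq_len(100L)) {
          chr <- sample.int(config$n_chromosomes, 1L)
          start <- sample.int(config$snps_per_chr - len + 1L, 1L)
          if (!.overlaps(occupied[[si]], chr, start, start + len - 1L)) {
            placed <- TRUE; break
          }
        }
        if (!placed)
          stop("could not place aberration without overlap; reduce fractions")
      }
      end <- start + len - 1L
      occupied[[si]] <- rbind(occupied[[si]],
                              data.frame(chr = chr, start = start, end = end))
      chr_name <- layout$chr_names[chr]
      gi <- (chr - 1L) * config$snps_per_chr + (start:end)  # genotype rows
      res <- .mutate_genotypes(cn_a[gi, si], cn_b[gi, si], ab$type)
      cn_a[gi, si] <- res$a
      cn_b[gi, si] <- res$b
      bp <- c(layout$snp_pos[start], layout$snp_pos[end])
      in_region <- ann$chromosome == chr_name & ann$position >= bp[1L] &
        ann$position <= bp[2L]
      normal[in_region, si] <- FALSE
      total_cn[in_region & !is_snp, si] <-
        max(0L, 2L + delta_total[[ab$type]])
      regions[[length(regions) + 1L]] <- data.frame(
        sample = si, chromosome = chr_name, start_bp = bp[1L],
        end_bp = bp[2L], type = ab$type, stringsAsFactors = FALSE)
    }
  }
  # genotype matrices are chromosome-major with ascending positions, which
  # is exactly the annotation order restricted to SNP probes
  total_cn[which(is_snp), ] <- cn_a + cn_b
  c(genotypes,
    list(cn_a = cn_a, cn_b = cn_b, cn_total = total_cn, normal = normal,
         regions = if (length(regions)) do.call(rbind, regions)
                   else data.frame(),
         annotation = ann))
}

.overlaps <- function(occ, chr, start, end) {
  if (is.null(occ)) return(FALSE)
  any(occ$chr == chr & occ$start <= end & occ$end >= start)
}

# somatic allele-copy transformation for one event type
.mutate_genotypes <- function(a, b, type) {
  het <- a == 1L & b == 1L
  coin <- stats::runif(length(a)) < 0.5      # fair coin per heterozygote
  switch(type,
    deletion = {
      a2 <- ifelse(het, ifelse(coin, 0L, 1L), pmax(a - (a >= b), 0L))
      b2 <- ifelse(het, ifelse(coin, 1L, 0L), pmax(b - (b > a), 0L))
      list(a = a2, b = b2)
    },
    gain = {
      a2 <- ifelse(het, ifelse(coin, 2L, 1L), a + (a >= b & a > 0L))
      b2 <- ifelse(het, ifelse(coin, 1L, 2L), b + (b > a))
      list(a = a2, b = b2)
    },
    loh = {
      a2 <- ifelse(het, ifelse(coin, 2L, 0L), a)
      b2 <- ifelse(het, ifelse(coin, 0L, 2L), b)
      list(a = a2, b = b2)
    },
    homozygous_deletion = list(a = 0L * a, b = 0L * b),
    amplification = {
      a2 <- ifelse(het, ifelse(coin, 3L, 1L), a + 2L * (a >= b & a > 0L))
      b2 <- ifelse(het, ifelse(coin, 1L, 3L), b + 2L * (b > a))
      list(a = a2, b = b2)
    },
    stop("unknown aberration type: ", type))
}

#' Render summarized allele signals from ground truth
#'
#' Applies the signal model documented in \code{\link{sim_config}}:
#' per-probe proportionality constants, batch factors, purity mixing with
#' the germline genotype, multiplicative noise and the additive floor.
#'
#' @param truth output of \code{\link{apply_aberrations}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list with \code{signals} (a \code{\link{signal_set}}) and
#'   \code{batch} (integer batch label per sample).
#' @export
render_signals <- function(truth, config) {
  old <- .derived_rng(config$seed + 2L)
  on.exit(.restore_rng(old))
  ann <- truth$annotation
  I <- config$n_samples
  J <- nrow(truth$cn_a)
  purity <- rep(config$purity, length.out = I)
  batch <- rep(seq_len(config$n_batches),
               each = ceiling(I / config$n_batches))[seq_len(I)]
  sample_ids <- sprintf("S%03d", seq_len(I))
  is_snp <- ann$probe_class == "SNP"
  snp_ids <- ann$probe_id[is_snp]
  cn_ids <- ann$probe_id[!is_snp]
  Jcn <- length(cn_ids)

  phi_snp <- exp(stats::rnorm(J, 0, config$probe_log_sd))
  phi_cn <- exp(stats::rnorm(Jcn, 0, config$probe_log_sd))
  bf_snp <- matrix(exp(stats::rnorm(J * config$n_batches, 0,
                                    config$batch_log_sd)), J)
  bf_cn <- matrix(exp(stats::rnorm(Jcn * config$n_batches, 0,
                                   config$batch_log_sd)), max(Jcn, 0L))

  pm <- matrix(purity, J, I, byrow = TRUE)
  eff_a <- pm * truth$cn_a + (1 - pm) * truth$germ_a
  eff_b <- pm * truth$cn_b + (1 - pm) * truth$germ_b
  bmat <- bf_snp[, batch, drop = FALSE]
  noise <- function(n) exp(stats::rnorm(n, 0, config$noise_sd))
  theta_a <- phi_snp * bmat * eff_a * matrix(noise(J * I), J) +
    config$signal_floor * phi_snp
  theta_b <- phi_snp * bmat * eff_b * matrix(noise(J * I), J) +
    config$signal_floor * phi_snp
  # genotype matrices are chromosome-major; that equals annotation order
  # restricted to SNPs, so rownames can be assigned directly
  dimnames(theta_a) <- list(snp_ids, sample_ids)
  dimnames(theta_b) <- list(snp_ids, sample_ids)

  theta_cn <- NULL
  if (Jcn > 0) {
    cn_tot <- truth$cn_total[cn_ids, , drop = FALSE]
    pmc <- matrix(purity, Jcn, I, byrow = TRUE)
    eff_t <- pmc * cn_tot + (1 - pmc) * 2
    theta_cn <- phi_cn * bf_cn[, batch, drop = FALSE] * eff_t *
      matrix(noise(Jcn * I), Jcn) + config$signal_floor * phi_cn
    dimnames(theta_cn) <- list(cn_ids, sample_ids)
  }
  list(signals = signal_set(theta_a, theta_b, ann, theta_cn), batch = batch)
}

#' Simulate a complete synthetic SNP-array dataset
#'
#' Composes genotype simulation, aberration placement and signal
#' rendering. Deterministic for a fixed seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{signals} (a \code{\link{signal_set}}),
#'   \code{truth} (see \code{\link{apply_aberrations}}, plus
#'   \code{batch}) and \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genotypes <- simulate_genotypes(config)
  truth <- apply_aberrations(genotypes, config)
  rendered <- render_signals(truth, config)
  truth$batch <- rendered$batch
  colnames(truth$normal) <- rendered$signals$sample_ids
  colnames(truth$cn_total) <- rendered$signals$sample_ids
  list(signals = rendered$signals, truth = truth, config = config)
}
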