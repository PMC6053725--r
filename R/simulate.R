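# Synthetic-data generator: genome annotation, per-track read intervals,
# peaks and RPKM expression tables with a planted mark-to-expression
# association, so the whole pipeline is testable without any external
# accession. Counts are negative binomial (ChIP tag counts are
# overdispersed); a planted subset of genes carries a log2-scale
# condition shift in the responsive genotype and informative marks only.

#' Simulation configuration
#'
#' The stated world of the generator. Defaults: 1000 genes on 2
#' chromosomes; genotypes `C` (wild type) and `e` (insensitive mutant);
#' marks `K9`, `K14`, `K23`; conditions `A` (air) and `C` (ethylene); 10%
#' planted up / 15% planted down (more down- than up-regulation, as in the
#' ethylene response); effect size 2 on the log2 scale (4-fold); the
#' planted effect lives in genotype `C` and marks `K14`/`K23` (the marks
#' that respond to the treatment, with `K9` as a condition-independent
#' baseline mark); 200k reads per track with NB dispersion 0.1; 2
#' expression replicates per condition with log-normal replicate noise.
#'
#' @param n_genes,n_chromosomes genome size.
#' @param genotypes,marks,conditions vocabularies (conditions: exactly 2).
#' @param frac_up,frac_down planted fractions (sum <= 1).
#' @param effect_size log2 shift of the planted differential signal.
#' @param informative_marks subset of `marks` carrying the effect.
#' @param responsive_genotype genotype in which the effect is planted.
#' @param read_depth reads per track.
#' @param noise_dispersion NB overdispersion (variance = mu + d * mu^2).
#' @param seed master seed; every stochastic component draws from its own
#'   deterministically derived stream.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000L, n_chromosomes = 2L,
                              genotypes = c("C", "e"),
                              marks = c("K9", "K14", "K23"),
                              conditions = c("A", "C"),
                              frac_up = 0.10, frac_down = 0.15,
                              effect_size = 2,
                              informative_marks = c("K14", "K23"),
                              responsive_genotype = "C",
                              read_depth = 200000L,
                              noise_dispersion = 0.1,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              genotypes = genotypes, marks = marks, conditions = conditions,
              frac_up = frac_up, frac_down = frac_down,
              effect_size = effect_size,
              informative_marks = informative_marks,
              responsive_genotype = responsive_genotype,
              read_depth = as.integer(read_depth),
              noise_dispersion = noise_dispersion, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  if (cfg$n_genes < 1L || cfg$n_chromosomes < 1L)
    stop("n_genes and n_chromosomes must be positive")
  if (cfg$n_genes < cfg$n_chromosomes)
    stop("need at least one gene per chromosome")
  if (length(cfg$marks) == 0L) stop("mark list must not be empty")
  if (length(cfg$conditions) != 2L) stop("exactly two conditions required")
  if (cfg$frac_up < 0 || cfg$frac_down < 0 ||
      cfg$frac_up + cfg$frac_down > 1)
    stop("invalid fractions: need frac_up, frac_down >= 0 and sum <= 1")
  if (!all(cfg$informative_marks %in% cfg$marks))
    stop("informative_marks must be a subset of marks")
  if (!cfg$responsive_genotype %in% cfg$genotypes)
    stop("responsive_genotype must be one of the genotypes")
  if (cfg$effect_size < 0) stop("effect_size must be nonnegative")
  if (cfg$read_depth < 1L || cfg$noise_dispersion <= 0)
    stop("read_depth and noise_dispersion must be positive")
  invisible(cfg)
}

# Non-overlapping gene models with intergenic gaps >= 3 kb.
simulate_genes <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "genes"), {
    n <- cfg$n_genes
    per_chrom <- rep(ceiling(n / cfg$n_chromosomes), cfg$n_chromosomes)
    per_chrom[cfg$n_chromosomes] <- n - sum(per_chrom[-cfg$n_chromosomes])
    genes <- vector("list", n)
    chrom_lengths <- numeric(cfg$n_chromosomes)
    names(chrom_lengths) <- paste0("chr", seq_len(cfg$n_chromosomes))
    gi <- 0L
    width <- nchar(as.character(n))
    for (ci in seq_len(cfg$n_chromosomes)) {
      pos <- 2000
      for (k in seq_len(per_chrom[ci])) {
        gi <- gi + 1L
        n_ex <- sample(1:6, 1L, prob = c(.15, .25, .25, .15, .10, .10))
        ex_len <- sample(100:600, n_ex, replace = TRUE)
        in_len <- if (n_ex > 1L) sample(80:400, n_ex - 1L, replace = TRUE)
                  else integer(0)
        starts <- pos + cumsum(c(0, ex_len[-n_ex] + in_len))
        exons <- interval_matrix(starts, starts + ex_len)
        gid <- sprintf("gene%0*d", width, gi)
        strand <- sample(c("+", "-"), 1L)
        trim5 <- sample(30:150, 1L)
        trim3 <- sample(30:150, 1L)
        gs <- exons[1L, 1]; ge <- exons[n_ex, 2]
        cs <- gs + trim5; ce <- ge - trim3
        if (ce - cs < 60) { cs <- NA_real_; ce <- NA_real_ }
        genes[[gi]] <- gene_model(gene_id = gid, chrom = names(chrom_lengths)[ci],
                                  strand = strand, exons = exons,
                                  cds_start = cs, cds_end = ce)
        pos <- ge + 3000 + sample(0:5000, 1L)
      }
      chrom_lengths[ci] <- pos + 2000
    }
    names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
    list(genes = genes, chrom_lengths = chrom_lengths)
  })
}

simulate_labels <- function(cfg, gene_ids) {
  with_seed(derive_seed(cfg$seed, "labels"), {
    n <- length(gene_ids)
    n_up <- round_half_up(cfg$frac_up * n)
    n_down <- round_half_up(cfg$frac_down * n)
    planted <- sample(gene_ids, n_up + n_down)
    label <- rep("none", n)
    names(label) <- gene_ids
    label[planted[seq_len(n_up)]] <- "up"
    label[planted[n_up + seq_len(n_down)]] <- "down"
    data.table::data.table(gene_id = gene_ids, label = unname(label))
  })
}

# Per-gene log2 expression shift in a given genotype: +/- effect for planted
# genes in the responsive genotype, 0 elsewhere.
planted_shift <- function(cfg, labels, genotype) {
  s <- numeric(nrow(labels))
  if (genotype == cfg$responsive_genotype) {
    s[labels$label == "up"] <- cfg$effect_size
    s[labels$label == "down"] <- -cfg$effect_size
  }
  stats::setNames(s, labels$gene_id)
}

simulate_expression <- function(cfg, labels, baseline) {
  out <- list()
  conds <- cfg$conditions
  for (g in cfg$genotypes) {
    shift <- planted_shift(cfg, labels, g)
    with_seed(derive_seed(cfg$seed, paste0("expr.", g)), {
      tab <- data.table::data.table(gene_id = labels$gene_id)
      mean_a <- baseline
      mean_b <- baseline * 2^shift
      for (rep_i in 1:2)
        tab[[paste0("rpkm_rep", rep_i, "_", conds[1L])]] <-
          round(mean_a * stats::rlnorm(length(baseline), 0, 0.1), 4)
      for (rep_i in 1:2)
        tab[[paste0("rpkm_rep", rep_i, "_", conds[2L])]] <-
          round(mean_b * stats::rlnorm(length(baseline), 0, 0.1), 4)
      out[[g]] <- tab
    })
  }
  out
}

# Enrichment region of a gene: gene span plus 1500 bp upstream and 200 bp
# downstream (strand-aware), clipped to the chromosome.
gene_region <- function(g, chrom_length) {
  span <- c(g$exons[1L, 1], g$exons[nrow(g$exons), 2])
  if (g$strand == "+") iv <- c(span[1] - 1500, span[2] + 200)
  else iv <- c(span[1] - 200, span[2] + 1500)
  c(max(0, iv[1]), min(chrom_length, iv[2]))
}

simulate_tracks <- function(cfg, geno, labels, baseline) {
  genes <- geno$genes
  chrom_lengths <- geno$chrom_lengths
  n <- length(genes)
  regions <- t(vapply(genes, function(g)
    gene_region(g, chrom_lengths[[g$chrom]]), numeric(2)))
  span_kb <- (regions[, 2] - regions[, 1]) / 1000
  gene_chrom <- vapply(genes, `[[`, character(1), "chrom")
  read_len <- 50L
  tracks <- list()
  peaks <- list()
  size_nb <- 1 / cfg$noise_dispersion
  for (g in cfg$genotypes) for (mk in cfg$marks) {
    # per-gene acetylation propensity: coupled to expression baseline,
    # shared across the two conditions of this genotype x mark
    acet <- with_seed(derive_seed(cfg$seed, paste("acet", g, mk)),
                      (baseline / 8)^0.3 *
                        stats::rlnorm(n, 0, 0.4))
    shift <- planted_shift(cfg, labels, g)
    responsive_mark <- mk %in% cfg$informative_marks
    # one peak locus per enriched gene, shared across conditions so that
    # differential analysis sees common peaks
    peak_loci <- with_seed(derive_seed(cfg$seed, paste("loci", g, mk)), {
      enriched <- which(acet > stats::quantile(acet, 0.3))
      tss <- vapply(genes[enriched], function(gm)
        if (gm$strand == "+") gm$exons[1L, 1]
        else gm$exons[nrow(gm$exons), 2], numeric(1))
      w <- pmax(150, round(stats::rnorm(length(enriched), 500, 100)))
      center <- tss + sample(-100:300, length(enriched), replace = TRUE)
      data.table::data.table(
        gene = enriched, chrom = gene_chrom[enriched],
        start = pmax(0, round(center - w / 2)),
        end = round(center + w / 2))
    })
    for (ci in seq_along(cfg$conditions)) {
      cond <- cfg$conditions[ci]
      cond_shift <- if (ci == 2L && responsive_mark) shift else 0 * shift
      w_gene <- span_kb * acet * 2^cond_shift
      mu <- 0.95 * cfg$read_depth * w_gene / sum(w_gene)
      key <- track_key(g, mk, cond)
      tracks[[key]] <- with_seed(
        derive_seed(cfg$seed, paste("reads", g, mk, cond)), {
          n_reads <- stats::rnbinom(n, mu = mu, size = size_nb)
          gene_of_read <- rep.int(seq_len(n), n_reads)
          lo <- regions[gene_of_read, 1]
          hi <- pmax(lo + 1, regions[gene_of_read, 2] - read_len)
          starts <- floor(lo + stats::runif(length(gene_of_read)) * (hi - lo))
          n_bg <- round(0.05 * cfg$read_depth)
          bg_chrom <- sample(names(chrom_lengths), n_bg, replace = TRUE,
                             prob = chrom_lengths / sum(chrom_lengths))
          bg_start <- floor(stats::runif(n_bg) *
                              (chrom_lengths[bg_chrom] - read_len))
          dt <- data.table::data.table(
            chrom = c(gene_chrom[gene_of_read], bg_chrom),
            start = c(starts, bg_start))
          dt$end <- dt$start + read_len
          data.table::setorderv(dt, c("chrom", "start"))
          dt$name <- sprintf("%s_read%07d", key, seq_len(nrow(dt)))
          dt$score <- 0L
          dt$strand <- "."
          dt
        })
      peaks[[key]] <- with_seed(
        derive_seed(cfg$seed, paste("peaks", g, mk, cond)), {
          pk <- data.table::copy(peak_loci)
          dens <- mu[pk$gene] / span_kb[pk$gene]   # reads per kb of region
          fe <- pmax(1.1, 1.5 + dens / stats::median(dens) *
                       stats::rlnorm(nrow(pk), 0, 0.15))
          pk$fold_enrichment <- round(fe, 3)
          pk$name <- sprintf("%s_peak%05d", key, seq_len(nrow(pk)))
          pk$score <- pmin(1000L, as.integer(round(fe * 100)))
          pk$strand <- "."
          pk$pvalue_log10 <- 4
          pk$qvalue_log10 <- 2
          pk$summit <- as.integer(floor((pk$end - pk$start) / 2))
          pk$gene <- NULL
          data.table::setorderv(pk, c("chrom", "start"))
          pk
        })
    }
  }
  list(tracks = tracks, peaks = peaks)
}

#' Generate a synthetic dataset bundle
#'
#' Produces gene models, per-track read intervals, per-track peaks,
#' replicate expression tables per genotype and the planted truth labels.
#' The same configuration (same seed) always regenerates identical output.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given the bundle is also written
#'   via [write_dataset()].
#' @return list with `config`, `genes`, `chrom_lengths`, `labels`
#'   (data.table gene_id/label), `expression` (list per genotype), `tracks`
#'   and `peaks` (lists keyed `"{genotype}.{mark}.{condition}"`).
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  validate_config(config)
  geno <- simulate_genes(config)
  labels <- simulate_labels(config, names(geno$genes))
  baseline <- with_seed(derive_seed(config$seed, "baseline"),
                        stats::rlnorm(config$n_genes, log(8), 1))
  expression <- simulate_expression(config, labels, baseline)
  tp <- simulate_tracks(config, geno, labels, baseline)
  bundle <- list(config = config, genes = geno$genes,
                 chrom_lengths = geno$chrom_lengths, labels = labels,
                 expression = expression, tracks = tp$tracks,
                 peaks = tp$peaks)
  if (!is.null(out_dir)) write_dataset(bundle, out_dir)
  bundle
}

#' Write a synthetic bundle to standard formats
#'
#' Gene models as GFF3 + BED12, reads as BED6 (one file per track), peaks as
#' narrowPeak, expression as TSV per genotype, truth labels as TSV.
#'
#' @param bundle from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(bundle$genes, file.path(dir, "genes.gff3"))
  write_bed12(bundle$genes, file.path(dir, "genes.bed12"))
  for (key in names(bundle$tracks))
    write_bed_reads(bundle$tracks[[key]],
                    file.path(dir, paste0("reads_", key, ".bed")))
  for (key in names(bundle$peaks))
    write_narrowpeak(bundle$peaks[[key]],
                     file.path(dir, paste0("peaks_", key, ".narrowPeak")))
  for (g in names(bundle$expression))
    write_tsv_table(bundle$expression[[g]],
                    file.path(dir, paste0("expression_", g, ".tsv")))
  write_tsv_table(bundle$labels, file.path(dir, "labels_truth.tsv"))
  chl <- data.table::data.table(chrom = names(bundle$chrom_lengths),
                                length = as.integer(bundle$chrom_lengths))
  write_tsv_table(chl, file.path(dir, "chrom_lengths.tsv"))
  invisible(dir)
}

#' Simulate a labeled feature matrix directly
#'
#' A bare genes x features Gaussian matrix for classifier checks: the first
#' `n_informative` features ("signal...") carry a class-dependent mean
#' shift of `effect_size` (plus/minus `effect_size/2` for up/down), the
#' rest ("noise...") are pure standard normal. Classes are balanced.
#'
#' @param n_genes,n_features,n_informative dimensions.
#' @param effect_size total mean separation of informative features.
#' @param seed RNG seed.
#' @return list with `x` (matrix) and `y` (labels "up"/"down").
#' @export
simulate_labeled_features <- function(n_genes = 1000L, n_features = 100L,
                                      n_informative = 10L, effect_size = 2,
                                      seed = 1L) {
  stopifnot(n_informative <= n_features)
  with_seed(seed, {
    y <- rep(c("up", "down"), length.out = n_genes)
    x <- matrix(stats::rnorm(n_genes * n_features), n_genes, n_features)
    sgn <- ifelse(y == "up", 1, -1)
    if (n_informative > 0L)
      x[, seq_len(n_informative)] <-
        x[, seq_len(n_informative)] + sgn * effect_size / 2
    colnames(x) <- c(sprintf("signal%02d", seq_len(n_informative)),
                     sprintf("noise%03d", seq_len(n_features - n_informative)))
    rownames(x) <- sprintf("gene%04d", seq_len(n_genes))
    list(x = x, y = y)
  })
}

#' Count track reads overlapping each peak
#'
#' Restores the per-condition peak read counts needed for differential
#' analysis when peaks arrive as narrowPeak files (which carry no counts).
#'
#' @param peaks data.table(chrom, start, end, ...).
#' @param reads data.table of read intervals.
#' @return `peaks` with a `count` column.
#' @export
add_peak_counts <- function(peaks, reads) {
  peaks <- data.table::as.data.table(peaks)
  if (nrow(peaks) == 0L) {
    peaks$count <- numeric(0)
    return(peaks)
  }
  ov <- GenomicRanges::countOverlaps(to_granges(peaks), to_granges(reads),
                                     minoverlap = 1L)
  peaks$count <- as.numeric(ov)
  peaks
}
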