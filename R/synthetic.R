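# Synthetic data with planted truth.
#
# The generators emulate the data properties the discovery pipeline relies
# on: genomes carrying planted pre-miRNA hairpins with perfect 20-bp stems
# and 2-nt 3' overhangs on both duplex strands; read libraries concentrated
# on the mature/star arms with dominant 5' ends, adapter suffixes, Phred
# error profiles and a piRNA-like 26-31 nt fraction with 5'-U bias;
# transcripts with a long ORF and 3' UTRs holding planted high- and
# low-accessibility target sites; and a small GO DAG with one truly enriched
# term. Every generator is deterministic given the seed (one RNG stream per
# stage, seeded seed + stage offset, so stages can be regenerated
# independently).
#
# Hairpin construction detail: the mature arm is drawn from {A,T} for its
# first mature_len-2 bases with a C-C 3' dinucleotide, the loop is poly-A
# and the star arm is the reverse complement of the paired mature prefix
# plus an unpaired C-run overhang. With these alphabets the precursor
# contains no G at all, so neither C overhang can pair anywhere inside the
# precursor, and the maximum-weight fold of the read-delimited precursor
# recovers the designed duplex geometry exactly (the A:U stem is the unique
# maximum-pairing registration; any shift or loop pairing loses weight or is
# broken by the 5'-most-partner traceback rule).

#' Simulation configuration
#'
#' Defaults encode the study conditions the package is tested under:
#' 20 hairpins at a log-normal read depth (median 200), 90% 5'-end purity,
#' 2-nt overhangs with one conserved 3-nt-overhang hairpin exercising the
#' conservation rescue, 20% noise reads and a 25% piRNA-like fraction with
#' a 0.9 5'-U probability.
#'
#' @param seed integer RNG seed.
#' @param n_hairpins planted hairpins (default 20).
#' @param mature_len mature arm length in nt (>= 18; default 22).
#' @param loop_len hairpin loop length (>= 3; default 15).
#' @param flank_len genomic flank on each side of a hairpin (default 200).
#' @param reads_median,reads_sdlog log-normal read count per hairpin
#'   (median 200, sdlog 0.5).
#' @param five_prime_purity probability a mature/star read starts at the
#'   arm's 5' end (default 0.9).
#' @param overhang designed 3' overhang in nt (default 2).
#' @param n_rescue hairpins planted with a 3-nt overhang and a conserved
#'   mature sequence (default 1).
#' @param noise_read_fraction fraction of reads that are noise or
#'   contaminant fragments (default 0.2).
#' @param pirna_fraction fraction of reads that are 26-31 nt piRNA-like
#'   (default 0.25).
#' @param pirna_u_prob probability a piRNA-like read starts with T
#'   (default 0.9).
#' @param adapter3 3' adapter appended to short inserts.
#' @param instrument_len sequenced read length (default 36).
#' @param phred_mean,phred_3p Phred profile: mean at the 5' end decaying to
#'   `phred_3p` at the 3' end (defaults 32 and 18).
#' @param n_transcripts simulated transcripts (default 30).
#' @param n_strong,n_weak,n_short_utr planted strong/weak target-site and
#'   short-UTR transcripts (defaults 10, 10, 3).
#' @param utr_len nominal 3' UTR length (default 150).
#' @param n_go_terms GO DAG size (default 30).
#' @param n_genes annotation universe size (default 1000).
#' @param study_size enrichment study-set size (default 50).
#' @param enriched_term_effect sampling weight multiplier for genes of the
#'   enriched term (> 1; default 5).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_hairpins = 20, mature_len = 22,
                       loop_len = 15, flank_len = 200, reads_median = 200,
                       reads_sdlog = 0.5, five_prime_purity = 0.9,
                       overhang = 2, n_rescue = 1,
                       noise_read_fraction = 0.2, pirna_fraction = 0.25,
                       pirna_u_prob = 0.9,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       instrument_len = 36, phred_mean = 32, phred_3p = 18,
                       n_transcripts = 30, n_strong = 10, n_weak = 10,
                       n_short_utr = 3, utr_len = 150, n_go_terms = 30,
                       n_genes = 1000, study_size = 50,
                       enriched_term_effect = 5) {
  cfg <- as.list(environment())
  if (n_hairpins <= 0) stop("n_hairpins must be positive", call. = FALSE)
  if (mature_len < 18) stop("mature_len must be >= 18", call. = FALSE)
  if (loop_len < 3) stop("loop_len must be >= 3", call. = FALSE)
  fr <- c(five_prime_purity, noise_read_fraction, pirna_fraction,
          pirna_u_prob)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (noise_read_fraction + pirna_fraction >= 1)
    stop("noise + piRNA fractions must leave room for hairpin reads",
         call. = FALSE)
  if (enriched_term_effect <= 1)
    stop("enriched_term_effect must exceed 1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# mature arm: first mature_len-2 bases from {A,T}, then "CC"; the G-free
# precursor alphabet leaves both C overhangs without any pairing partner
sim_mature <- function(mature_len) {
  paste0(random_dna(mature_len - 2, bases = c("A", "T")), "CC")
}

# star arm: reverse complement of the paired mature prefix plus an
# unpaired C-run 3' overhang of the requested length
sim_star <- function(mature, overhang) {
  m <- nchar(mature)
  paste0(revcomp(substr(mature, 1, m - 2)),
         paste(rep("C", overhang), collapse = ""))
}

#' Simulate a genome with planted pre-miRNA hairpins
#'
#' Each hairpin (mature + loop + star, the star being the shifted reverse
#' complement of the mature) sits in its own contig between random flanks;
#' half the hairpins are planted on the minus strand. `n_rescue` hairpins
#' get a 3-nt 3' overhang and a mature sequence that is a close (2-mismatch,
#' 1-nt-offset) match to an entry of the generated known-miRNA reference,
#' exercising the conservation rescue path.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (records data.frame), `known` (known-miRNA
#'   reference records) and `truth` (data.frame of planted hairpins:
#'   contig, strand, genomic coordinates, mature/star sequences, overhang,
#'   conserved flag).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  n <- config$n_hairpins
  mlen <- config$mature_len
  genome <- list(); truth <- list(); known <- list()
  for (i in seq_len(n)) {
    rescue <- i > n - config$n_rescue
    ov <- if (rescue) 3L else config$overhang
    mature <- sim_mature(mlen)
    star <- sim_star(mature, ov)
    loop <- paste(rep("A", config$loop_len), collapse = "")
    hairpin <- paste0(mature, loop, star)
    strand <- if (i %% 2 == 0) "-" else "+"
    fl <- random_dna(config$flank_len)
    fr <- random_dna(config$flank_len)
    insert <- if (strand == "+") hairpin else revcomp(hairpin)
    contig_id <- sprintf("contig%02d", i)
    genome[[i]] <- data.frame(id = contig_id, desc = "",
                              seq = paste0(fl, insert, fr),
                              stringsAsFactors = FALSE)
    hp_start <- config$flank_len                       # 0-based
    hp_len <- nchar(hairpin)
    # genomic (0-based) 5' coordinate of the mature and star arms
    if (strand == "+") {
      mature5 <- hp_start
      star5 <- hp_start + mlen + config$loop_len
    } else {
      mature5 <- hp_start + hp_len - 1L
      star5 <- hp_start + hp_len - 1L - mlen - config$loop_len
    }
    if (rescue) {
      # reference entry: 1-nt offset, 2 mismatches from the planted mature
      ref <- paste0("A", substr(mature, 1, mlen - 1))
      rv <- seq_chars(ref)
      for (p in c(5L, 11L))
        rv[p] <- sample(setdiff(c("A", "C", "G", "T"), rv[p]), 1)
      known[[length(known) + 1]] <- data.frame(
        id = sprintf("nve-miR-%d", 2100 + i), desc = "synthetic reference",
        seq = paste(rv, collapse = ""), stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(
      hairpin = sprintf("hp%02d", i), contig = contig_id, strand = strand,
      hp_start = hp_start, hp_end = hp_start + hp_len,
      mature5 = mature5, star5 = star5, mature_seq = mature,
      star_seq = star, overhang = ov, conserved = rescue,
      stringsAsFactors = FALSE)
  }
  list(genome = do.call(rbind, genome),
       known = if (length(known)) do.call(rbind, known) else
         data.frame(id = character(0), desc = character(0),
                    seq = character(0)),
       truth = do.call(rbind, truth))
}

# extract a read of `len` nt whose 5' base sits at 0-based position p5
genome_read <- function(contig_seq, p5, len, strand) {
  if (strand == "+") substr(contig_seq, p5 + 1, p5 + len)
  else revcomp(substr(contig_seq, p5 - len + 2, p5 + 1))
}

# Phred profile: linear decay from phred_mean to phred_3p across the read
sim_quals <- function(len, config) {
  mu <- config$phred_mean -
    (config$phred_mean - config$phred_3p) * (seq_len(len) - 1) /
    max(1, config$instrument_len - 1)
  q <- round(rnorm(len, mu, 3))
  pmin(pmax(q, 3L), 40L)
}

# substitution errors at the per-base Phred rate
apply_errors <- function(seq, quals) {
  p <- 10^(-quals / 10)
  hit <- runif(length(p)) < p
  if (!any(hit)) return(seq)
  sv <- seq_chars(seq)
  for (i in which(hit))
    sv[i] <- sample(setdiff(c("A", "C", "G", "T"), sv[i]), 1)
  paste(sv, collapse = "")
}

# finished instrument read: insert + 3' adapter fill + qualities + errors
finish_read <- function(id, insert, config) {
  if (nchar(insert) < config$instrument_len) {
    if (is.null(config$adapter3) || nchar(config$adapter3) == 0)
      stop("adapter3 required when inserts are shorter than the read length",
           call. = FALSE)
    fill <- config$instrument_len - nchar(insert)
    raw <- paste0(insert, substr(config$adapter3, 1, fill))
  } else {
    raw <- substr(insert, 1, config$instrument_len)
  }
  q <- sim_quals(nchar(raw), config)
  c(id = id, seq = apply_errors(raw, q), qual = phred_encode(q))
}

reads_frame <- function(lst) {
  m <- do.call(rbind, lst)
  data.frame(id = m[, "id"], seq = m[, "seq"], qual = m[, "qual"],
             stringsAsFactors = FALSE)
}

#' Simulate a small-RNA read library over a planted genome
#'
#' Mature- and star-arm reads start at the arm's 5' end with probability
#' `five_prime_purity` (otherwise offset by 1-2 nt); loop fragments, a
#' piRNA-like 26-31 nt genomic fraction with 5'-U bias, random noise reads
#' and contaminant fragments complete the library. The 3' adapter is
#' appended to short inserts and Phred-profiled substitution errors are
#' injected.
#'
#' @param genome,truth from [simulate_genome()].
#' @param config a [sim_config()].
#' @param contaminants contaminant records used for fragment reads
#'   (default: the bundled synthetic rRNA/tRNA mock).
#' @return list with `reads` (data.frame `id`, `seq`, `qual`) and `labels`
#'   (data.frame `id`, `origin`, `hairpin`).
#' @export
simulate_reads <- function(genome, truth, config,
                           contaminants = read_fasta(system.file(
                             "extdata", "synthetic_contaminants.fasta",
                             package = "coralmir"))) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 202L)
  reads <- list(); labels <- list()
  rid <- 0L
  emit <- function(insert, origin, hairpin = NA_character_) {
    rid <<- rid + 1L
    id <- sprintf("read%06d", rid)
    reads[[rid]] <<- finish_read(id, insert, config)
    labels[[rid]] <<- c(id = id, origin = origin, hairpin = hairpin)
  }
  jitter5 <- function(p5, strand) {
    if (runif(1) < config$five_prime_purity) return(p5)
    off <- sample(c(-2L, -1L, 1L, 2L), 1)
    if (strand == "+") p5 + off else p5 - off
  }
  n_hp_reads <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    ctg <- genome$seq[genome$id == tr$contig]
    n_i <- max(10L, round(rlnorm(1, log(config$reads_median),
                                 config$reads_sdlog)))
    n_mat <- round(0.7 * n_i); n_star <- round(0.2 * n_i)
    n_loop <- n_i - n_mat - n_star
    mlen <- nchar(tr$mature_seq); slen <- nchar(tr$star_seq)
    for (r in seq_len(n_mat))
      emit(genome_read(ctg, jitter5(tr$mature5, tr$strand), mlen,
                       tr$strand), "mature", tr$hairpin)
    for (r in seq_len(n_star))
      emit(genome_read(ctg, jitter5(tr$star5, tr$strand), slen,
                       tr$strand), "star", tr$hairpin)
    loop5 <- if (tr$strand == "+") tr$mature5 + mlen else tr$mature5 - mlen
    for (r in seq_len(n_loop)) {
      off <- sample(0:3, 1)
      len <- sample(10:14, 1)
      p5 <- if (tr$strand == "+") loop5 + off else loop5 - off
      emit(genome_read(ctg, p5, len, tr$strand), "loop", tr$hairpin)
    }
    n_hp_reads <- n_hp_reads + n_i
  }
  other <- 1 - config$noise_read_fraction - config$pirna_fraction
  n_pirna <- round(n_hp_reads * config$pirna_fraction / other)
  n_noise_total <- round(n_hp_reads * config$noise_read_fraction / other)
  n_contam <- round(0.4 * n_noise_total)
  n_noise <- n_noise_total - n_contam
  for (r in seq_len(n_pirna)) {
    ci <- sample(nrow(genome), 1)
    len <- sample(26:31, 1)
    L <- nchar(genome$seq[ci])
    start <- sample(0:(L - len), 1)
    s <- substr(genome$seq[ci], start + 1, start + len)
    first <- if (runif(1) < config$pirna_u_prob) "T" else
      sample(c("A", "C", "G"), 1)
    emit(paste0(first, substr(s, 2, len)), "pirna")
  }
  for (r in seq_len(n_noise))   # degradation noise sits below the piRNA band
    emit(random_dna(sample(18:25, 1)), "noise")
  if (n_contam > 0 && nrow(contaminants) > 0) {
    for (r in seq_len(n_contam)) {
      ci <- sample(nrow(contaminants), 1)
      len <- sample(21:30, 1)
      L <- nchar(contaminants$seq[ci])
      start <- sample(1:(L - len + 1), 1)
      emit(substr(contaminants$seq[ci], start, start + len - 1),
           "contaminant")
    }
  }
  reads <- reads_frame(reads)
  lm <- do.call(rbind, labels)
  labels <- data.frame(id = lm[, "id"], origin = lm[, "origin"],
                       hairpin = lm[, "hairpin"], stringsAsFactors = FALSE)
  # shuffle read order (library order carries no signal)
  ord <- sample(nrow(reads))
  list(reads = reads[ord, , drop = FALSE],
       labels = labels[ord, , drop = FALSE])
}

# non-stop codons for ORF bodies
safe_codons <- function() {
  all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# leader with no ATG and no pairing surprises: alphabet {C, A}
sim_leader <- function(n) random_dna(n, bases = c("C", "A"))

sim_orf <- function(n_codons = 120) {
  paste0("ATG", paste(sample(safe_codons(), n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

#' Simulate transcripts with planted miRNA target sites
#'
#' Each transcript is leader + ORF (ATG..TAA, no internal stop) + 3' UTR.
#' Strong sites are full reverse complements of a mature miRNA in an
#' unstructured (poly-A) UTR context, designed for ddG well below -12
#' kcal/mol. Weak sites expose only the seed complement, buried as one
#' strand of a G:C-clamped stem whose partner strand is enclosed by the
#' clamps, so the opening cost cancels most of the seed duplex energy and
#' the designed ddG stays above -5 kcal/mol. `n_short_utr` transcripts get
#' a 99-nt UTR (excluded by the UTR length filter); the remainder get
#' random UTRs.
#'
#' @param matures data.frame of mature miRNAs (`id`, `seq`).
#' @param config a [sim_config()].
#' @return list with `transcripts` (records data.frame) and `truth`
#'   (data.frame of planted sites: transcript, mirna, class,
#'   utr site coordinates).
#' @export
simulate_transcripts <- function(matures, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(matures) < 1) stop("need at least one mature miRNA",
                              call. = FALSE)
  if (any(nchar(matures$seq) < 9))
    stop("mature miRNA shorter than the seed span", call. = FALSE)
  set.seed(config$seed + 303L)
  n_strong <- min(config$n_strong, nrow(matures))
  n_weak <- min(config$n_weak, nrow(matures))
  transcripts <- list(); truth <- list()
  tid <- 0L
  add_tx <- function(utr, label, mirna = NA_character_,
                     site_start = NA_integer_, site_end = NA_integer_) {
    tid <<- tid + 1L
    id <- sprintf("tx%04d", tid)
    transcripts[[tid]] <<- data.frame(
      id = id, desc = label,
      seq = paste0(sim_leader(30), sim_orf(), utr),
      stringsAsFactors = FALSE)
    truth[[tid]] <<- data.frame(id = id, class = label, mirna = mirna,
                                site_start = site_start,
                                site_end = site_end,
                                stringsAsFactors = FALSE)
  }
  polyA <- function(n) paste(rep("A", n), collapse = "")
  for (i in seq_len(n_strong)) {
    m <- norm_dna(matures$seq[i])
    site <- revcomp(m)
    utr <- paste0(polyA(50), site, polyA(config$utr_len - 50 - nchar(site)))
    add_tx(utr, "strong", matures$id[i], 51L, 50L + nchar(site))
  }
  for (i in seq_len(n_weak)) {
    m <- norm_dna(matures$seq[i])
    seed <- substr(m, 2, 8)
    site <- revcomp(seed)
    c5 <- paste(rep("C", 5), collapse = "")
    g5 <- paste(rep("G", 5), collapse = "")
    stem <- paste0(c5, seed, c5, "AAAA", g5, site, g5)
    utr <- paste0(polyA(30), stem,
                  polyA(max(0, config$utr_len - 30 - nchar(stem))))
    s <- 30L + 5L + 7L + 5L + 4L + 5L + 1L   # site start within UTR
    add_tx(utr, "weak", matures$id[i], s, s + 6L)
  }
  for (i in seq_len(config$n_short_utr))
    add_tx(polyA(99), "short_utr")
  n_neutral <- config$n_transcripts - tid
  for (i in seq_len(max(0, n_neutral)))
    add_tx(random_dna(config$utr_len), "neutral")
  list(transcripts = do.call(rbind, transcripts),
       truth = do.call(rbind, truth))
}

#' Simulate a GO DAG with one enriched term
#'
#' Builds a random is_a DAG (`n_go_terms` terms, acyclic by construction),
#' annotates `n_genes` background genes uniformly, over-annotates one leaf
#' term, and samples a study set in which that term's genes carry sampling
#' weight `enriched_term_effect`.
#'
#' @param config a [sim_config()].
#' @param genes optional character vector of gene ids (default
#'   `g0001..`).
#' @return list with `dag` (an `ontology_dag`), `annotations` (direct
#'   gene/term pairs), `study`, `background` and `truth` (the enriched
#'   term id).
#' @export
simulate_ontology <- function(config, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_go_terms < 3) stop("need at least 3 GO terms", call. = FALSE)
  set.seed(config$seed + 404L)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(config$n_genes))
  ids <- sprintf("GO:%07d", 1000000 + seq_len(config$n_go_terms))
  parents <- setNames(vector("list", length(ids)), ids)
  parents[[ids[1]]] <- character(0)
  for (i in 2:length(ids)) {
    np <- if (i > 4 && runif(1) < 0.3) 2L else 1L
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1)], min(np, i - 1))
  }
  dag <- structure(list(
    terms = ids, names = setNames(sprintf("synthetic term %d",
                                          seq_along(ids)), ids),
    parents = parents,
    roots = ids[1]), class = "ontology_dag")

  enriched <- ids[length(ids)]               # parents-point-backwards leaf
  n_enriched_genes <- max(3L, round(0.1 * length(genes)))
  enriched_genes <- sample(genes, n_enriched_genes)
  ann <- list()
  for (g in genes) {
    terms <- sample(ids[-length(ids)], 3)
    ann[[length(ann) + 1]] <- data.frame(gene = g, term = terms,
                                         stringsAsFactors = FALSE)
  }
  ann[[length(ann) + 1]] <- data.frame(gene = enriched_genes,
                                       term = enriched,
                                       stringsAsFactors = FALSE)
  annotations <- unique(do.call(rbind, ann))
  w <- ifelse(genes %in% enriched_genes, config$enriched_term_effect, 1)
  study <- sample(genes, min(config$study_size, length(genes)),
                  prob = w)
  list(dag = dag, annotations = annotations, study = study,
       background = genes, truth = enriched)
}

#' Simulate decoy candidate windows
#'
#' Random-sequence windows with no designed stem, each given a modest
#' mature-arm read stack (50 reads, the configured 5' purity, no star
#' reads), emulating spurious degradation stacks at non-miRNA loci. Used to
#' measure the false-acceptance rate of the bona fide classifier.
#'
#' @param n number of decoy windows (default 200).
#' @param config a [sim_config()].
#' @param reads_per_decoy stack depth per decoy (default 50).
#' @return list with `genome` (one contig per decoy), `reads` and a
#'   `truth` data.frame naming the decoy contigs.
#' @export
simulate_decoys <- function(n = 200, config = sim_config(),
                            reads_per_decoy = 50) {
  set.seed(config$seed + 505L)
  mlen <- config$mature_len
  genome <- list(); reads <- list(); rid <- 0L
  for (i in seq_len(n)) {
    ctg <- sprintf("decoy%03d", i)
    L <- 2L * config$flank_len + mlen
    genome[[i]] <- data.frame(id = ctg, desc = "", seq = random_dna(L),
                              stringsAsFactors = FALSE)
    p5 <- config$flank_len
    for (r in seq_len(reads_per_decoy)) {
      rid <- rid + 1L
      off <- if (runif(1) < config$five_prime_purity) 0L else
        sample(c(-2L, -1L, 1L, 2L), 1)
      reads[[rid]] <- finish_read(sprintf("dread%06d", rid),
                                  substr(genome[[i]]$seq, p5 + 1 + off,
                                         p5 + off + mlen), config)
    }
  }
  list(genome = do.call(rbind, genome), reads = reads_frame(reads),
       truth = data.frame(contig = vapply(genome, `[[`, "", "id"),
                          stringsAsFactors = FALSE))
}
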