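# Deterministic, seed-controlled generators for every input the pipeline
# consumes: a toy genome with planted aquaporin genes, tandem and collinear
# duplications and decoys; codon pairs diverged at controlled
# synonymous/nonsynonymous rates; and expression/water/qPCR tables with
# planted signals. Every generator emits machine-readable truth labels.

HYDROPHOBIC_AA <- c("I", "L", "V", "F", "A", "M")
HYDROPHILIC_AA <- c("D", "E", "G", "K", "N", "Q", "R", "S", "T", "P", "H", "Y")

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# substitute a fraction of residues, respecting membrane topology: residues
# inside TM intervals stay strongly hydrophobic (so hydropathy detection is
# never destroyed by divergence), loop residues stay hydrophilic; protected
# positions (NPA motifs, annotated filter residues) never change
.mutate_protein <- function(seq, rate, tm = NULL, protected = integer(0)) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  in_tm <- rep(FALSE, n)
  if (!is.null(tm)) {
    for (r in seq_len(nrow(tm))) in_tm[tm[r, 1L]:tm[r, 2L]] <- TRUE
  }
  eligible <- setdiff(seq_len(n), protected)
  k <- min(length(eligible), round(rate * n))
  pos <- sample(eligible, k)
  for (p in pos) {
    pool <- if (in_tm[p]) c("I", "L", "V", "F") else HYDROPHILIC_AA
    pool <- setdiff(pool, chars[p])
    chars[p] <- sample(pool, 1L)
  }
  paste(chars, collapse = "")
}

# positions that must never mutate in a seed-derived protein: every
# annotated residue plus the full NPA triplets
.seed_protected <- function(seedrec) {
  pos <- seedrec$positions
  sort(unique(c(pos, pos[["NPA_LB"]] + 1:2, pos[["NPA_LE"]] + 1:2)))
}

.codons_for_aa <- function() {
  code <- .genetic_code()
  split(names(code), code)
}

# back-translate a protein choosing synonymous codons at random
.protein_to_cds <- function(protein) {
  tab <- .codons_for_aa()
  aa <- strsplit(protein, "")[[1L]]
  paste(vapply(aa, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

# edit a CDS so it encodes new_protein, changing only codons whose amino
# acid changed; then apply synonymous codon swaps at `syn_rate` of codons
.cds_for_mutant <- function(cds, old_protein, new_protein, syn_rate = 0) {
  tab <- .codons_for_aa()
  codons <- .split_codons(cds)
  oa <- strsplit(old_protein, "")[[1L]]
  na <- strsplit(new_protein, "")[[1L]]
  for (i in which(oa != na)) {
    opts <- tab[[na[i]]]
    codons[i] <- opts[sample.int(length(opts), 1L)]
  }
  if (syn_rate > 0) {
    k <- round(syn_rate * length(codons))
    for (i in sample(seq_along(codons), k)) {
      opts <- setdiff(tab[[na[i]]], codons[i])
      if (length(opts) > 0L) codons[i] <- opts[sample.int(length(opts), 1L)]
    }
  }
  paste(codons, collapse = "")
}

#' Labeled reference set derived from the bundled subfamily seeds
#'
#' Deterministic subgroup variants (two per subfamily except XIP) of the
#' synthetic seed scaffolds, for use as classification references and
#' homology-screen queries.
#'
#' @return data.frame: `ref_id`, `subfamily`, `subgroup`, `sequence`.
#' @export
aqp_reference_set <- function() {
  subgroup_sets <- list(PIP = c("PIP1", "PIP2"), TIP = c("TIP1", "TIP2"),
                        NIP = c("NIP1", "NIP2"), SIP = c("SIP1", "SIP2"),
                        XIP = "XIP1")
  rows <- list()
  for (fam in names(subgroup_sets)) {
    seed <- .AQP_SEEDS[[fam]]
    for (i in seq_along(subgroup_sets[[fam]])) {
      grp <- subgroup_sets[[fam]][i]
      seqv <- if (i == 1L) seed$sequence else .with_seed(
        7000L + match(fam, names(subgroup_sets)) * 10L + i,
        .mutate_protein(seed$sequence, 0.15, tm = seed$tm_truth,
                        protected = .seed_protected(seed))
      )
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = paste0("REF_", grp), subfamily = fam, subgroup = grp,
        sequence = seqv, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Specification for a synthetic genome
#'
#' Defaults mirror the structure of a small dicot aquaporin complement:
#' 38 family members split 14/13/8/2/1 over TIP/PIP/NIP/SIP/XIP across 8
#' chromosomes, one tandem duplicate pair and 7 segmental pairs carried by
#' collinear blocks, with unrelated decoy genes as background.
#'
#' @param seed RNG seed.
#' @param n_chromosomes Number of chromosomes.
#' @param background_per_chromosome Unrelated background genes per
#'   chromosome (decoys for the homology screen).
#' @param n_aqp Named integer vector of members per subfamily.
#' @param divergence Range (fraction of residues substituted) of subfamily
#'   members from their subgroup reference; high enough that only planted
#'   duplicate pairs exceed the duplicate-pair identity threshold.
#' @param pair_divergence Residue divergence between planted duplicate
#'   partners.
#' @param pair_syn_rate Fraction of partner codons receiving an extra
#'   synonymous substitution (plants Ks > Ka, i.e. purifying-selection
#'   signal).
#' @param tandem_pairs Number of tandem duplicate pairs.
#' @param tandem_separation_bp Gap between tandem partners (<= 100 kb).
#' @param segmental_pairs Number of segmental pairs (each inside its own
#'   collinear block).
#' @param block_anchors Anchor pairs per collinear block (>= 5).
#' @param max_member_identity Redraw margin: members of one subfamily that
#'   are not partners are regenerated until below this global identity (%).
#' @return List of class `GenomeSimSpec`.
#' @export
genome_sim_spec <- function(seed = 1L, n_chromosomes = 8L,
                            background_per_chromosome = 10L,
                            n_aqp = c(TIP = 14L, PIP = 13L, NIP = 8L,
                                      SIP = 2L, XIP = 1L),
                            divergence = c(0.40, 0.45),
                            pair_divergence = 0.08,
                            pair_syn_rate = 0.35,
                            tandem_pairs = 1L,
                            tandem_separation_bp = 20000L,
                            segmental_pairs = 7L,
                            block_anchors = 6L,
                            max_member_identity = 38) {
  if (tandem_separation_bp > 1e5) stop("tandem separation must be <= 100 kb")
  if (block_anchors < 5L) stop("blocks need at least 5 anchors")
  structure(as.list(environment()), class = "GenomeSimSpec")
}

# subgroup labels cycled over members of a subfamily
.subgroups_for <- function(fam, n) {
  refs <- aqp_reference_set()
  grps <- refs$subgroup[refs$subfamily == fam]
  rep(grps, length.out = n)
}

.random_decoy_protein <- function() {
  len <- sample(180:380, 1L)
  paste(sample(c(HYDROPHILIC_AA, "A", "C", "W"), len, TRUE), collapse = "")
}

# exon structure per subfamily (exon counts echo conserved family gene
# models: most TIPs two introns, most PIPs three)
.exon_count_for <- function(fam) {
  switch(fam, TIP = 3L, PIP = 4L, NIP = sample(2:5, 1L),
         SIP = sample(1:3, 1L), XIP = 4L, sample(1:4, 1L))
}

#' Simulate a genome with planted aquaporin genes and duplications
#'
#' @param spec A [genome_sim_spec()].
#' @param out_dir Optional directory; when given, `proteome.faa`,
#'   `cds.fna`, `genes.gff3` and `truth.tsv` are written there.
#' @return List: `prot` (a [proteome()]), `truth` (data.frame with one row
#'   per gene: subfamily, subgroup, divergence, role, partner, dup_type,
#'   block), `references` (the labeled reference set), `files` (paths or
#'   `NULL`).
#' @export
simulate_genome <- function(spec = genome_sim_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "GenomeSimSpec"))
  set.seed(spec$seed)
  refs <- aqp_reference_set()
  genes <- list()   # each: id, protein, cds, n_exons, role, fam, grp, ...
  add_gene <- function(g) genes[[length(genes) + 1L]] <<- g

  # --- subfamily members -------------------------------------------------
  member_seqs <- list()   # per subfamily, for the redraw margin
  aqp_ids <- character(0)
  for (fam in names(spec$n_aqp)) {
    n <- spec$n_aqp[[fam]]
    if (n == 0L) next
    grps <- .subgroups_for(fam, n)
    seedrec <- .AQP_SEEDS[[fam]]
    for (i in seq_len(n)) {
      ref_seq <- refs$sequence[refs$subgroup == grps[i]][1L]
      div <- runif(1L, spec$divergence[1L], spec$divergence[2L])
      prot_seq <- NULL
      for (attempt in 1:40) {
        # escalate divergence slightly on repeated draws so the identity
        # margin to earlier members stays guaranteed
        div_try <- min(0.55, div + 0.005 * (attempt - 1L))
        cand <- .mutate_protein(ref_seq, div_try, tm = seedrec$tm_truth,
                                protected = .seed_protected(seedrec))
        ok <- TRUE
        for (other in member_seqs[[fam]] %||% list()) {
          if (global_identity(cand, other) >= spec$max_member_identity) {
            ok <- FALSE; break
          }
        }
        if (ok) { prot_seq <- cand; div <- div_try; break }
      }
      if (is.null(prot_seq)) {
        stop("could not place subfamily member below the identity margin; ",
             "infeasible spec")
      }
      member_seqs[[fam]] <- c(member_seqs[[fam]] %||% list(), prot_seq)
      id <- sprintf("AQP_%s_%02d", fam, i)
      aqp_ids <- c(aqp_ids, id)
      add_gene(list(id = id, protein = prot_seq,
                    cds = .protein_to_cds(prot_seq),
                    n_exons = .exon_count_for(fam), role = "aqp",
                    fam = fam, grp = grps[i], divergence = div,
                    partner = NA, dup_type = NA, block = NA))
    }
  }

  # --- planted duplicate partners ---------------------------------------
  make_partner <- function(src, suffix, dup_type, block = NA) {
    seedrec <- .AQP_SEEDS[[src$fam]]
    p_prot <- .mutate_protein(src$protein, spec$pair_divergence,
                              tm = seedrec$tm_truth,
                              protected = .seed_protected(seedrec))
    p_cds <- .cds_for_mutant(src$cds, src$protein, p_prot,
                             syn_rate = spec$pair_syn_rate)
    list(id = paste0(src$id, suffix), protein = p_prot, cds = p_cds,
         n_exons = src$n_exons, role = "aqp", fam = src$fam, grp = src$grp,
         divergence = src$divergence, partner = src$id,
         dup_type = dup_type, block = block)
  }
  n_dup_src <- spec$tandem_pairs + spec$segmental_pairs
  if (n_dup_src > length(aqp_ids)) stop("not enough members to duplicate")
  dup_src_ids <- if (n_dup_src > 0L) sample(aqp_ids, n_dup_src) else character(0)
  tandem_src <- utils::head(dup_src_ids, spec$tandem_pairs)
  seg_src <- utils::tail(dup_src_ids, spec$segmental_pairs)

  tandem_partners <- list()
  for (sid in tandem_src) {
    src <- genes[[which(vapply(genes, `[[`, "", "id") == sid)]]
    p <- make_partner(src, "t", "tandem")
    genes[[which(vapply(genes, `[[`, "", "id") == sid)]]$dup_type <- "tandem"
    genes[[which(vapply(genes, `[[`, "", "id") == sid)]]$partner <- p$id
    tandem_partners[[sid]] <- p
    add_gene(p)
  }

  seg_partners <- list()
  for (bi in seq_along(seg_src)) {
    sid <- seg_src[bi]
    src <- genes[[which(vapply(genes, `[[`, "", "id") == sid)]]
    p <- make_partner(src, "s", "segmental", block = bi)
    genes[[which(vapply(genes, `[[`, "", "id") == sid)]]$dup_type <- "segmental"
    genes[[which(vapply(genes, `[[`, "", "id") == sid)]]$partner <- p$id
    genes[[which(vapply(genes, `[[`, "", "id") == sid)]]$block <- bi
    seg_partners[[sid]] <- p
    add_gene(p)
  }

  # --- collinear block scaffolding (background anchor pairs) ------------
  n_blocks <- spec$segmental_pairs
  block_sides <- list()
  for (bi in seq_len(n_blocks)) {
    side_a <- list(); side_b <- list()
    for (ai in seq_len(spec$block_anchors - 1L)) {
      base <- .random_decoy_protein()
      twin <- .mutate_protein(base, 0.05)
      ida <- sprintf("BLK%02d_A%02d", bi, ai)
      idb <- sprintf("BLK%02d_B%02d", bi, ai)
      base_cds <- .protein_to_cds(base)
      twin_cds <- .cds_for_mutant(base_cds, base, twin,
                                  syn_rate = spec$pair_syn_rate)
      ga <- list(id = ida, protein = base, cds = base_cds,
                 n_exons = sample(1:4, 1L), role = "block_anchor",
                 fam = NA, grp = NA, divergence = NA, partner = idb,
                 dup_type = "segmental", block = bi)
      gb <- list(id = idb, protein = twin, cds = twin_cds,
                 n_exons = ga$n_exons, role = "block_anchor",
                 fam = NA, grp = NA, divergence = NA, partner = ida,
                 dup_type = "segmental", block = bi)
      add_gene(ga); add_gene(gb)
      side_a[[length(side_a) + 1L]] <- ida
      side_b[[length(side_b) + 1L]] <- idb
    }
    # the AQP pair sits mid-block
    if (bi <= length(seg_src)) {
      sid <- seg_src[bi]
      at <- max(1L, (spec$block_anchors - 1L) %/% 2L)
      side_a <- append(side_a, sid, after = at)
      side_b <- append(side_b, seg_partners[[sid]]$id, after = at)
    }
    block_sides[[bi]] <- list(a = unlist(side_a), b = unlist(side_b))
  }

  # --- background decoys -------------------------------------------------
  n_background <- spec$n_chromosomes * spec$background_per_chromosome
  for (i in seq_len(n_background)) {
    p <- .random_decoy_protein()
    add_gene(list(id = sprintf("BG_%03d", i), protein = p,
                  cds = .protein_to_cds(p), n_exons = sample(1:4, 1L),
                  role = "decoy", fam = NA, grp = NA, divergence = NA,
                  partner = NA, dup_type = NA, block = NA))
  }

  # --- chromosome placement ---------------------------------------------
  ids <- vapply(genes, `[[`, "", "id")
  names(genes) <- ids
  placed <- c(unlist(lapply(block_sides, function(s) c(s$a, s$b))),
              unlist(lapply(tandem_partners, `[[`, "id")), tandem_src)
  loose <- setdiff(ids, placed)
  chrom_genes <- rep(list(character(0)), spec$n_chromosomes)

  # tandem pairs: adjacent slots on a random chromosome
  for (sid in tandem_src) {
    ch <- sample(spec$n_chromosomes, 1L)
    chrom_genes[[ch]] <- c(chrom_genes[[ch]], sid, tandem_partners[[sid]]$id)
  }
  # loose genes round-robin, shuffled
  loose <- sample(loose)
  for (i in seq_along(loose)) {
    ch <- ((i - 1L) %% spec$n_chromosomes) + 1L
    chrom_genes[[ch]] <- c(chrom_genes[[ch]], loose[i])
  }
  # blocks: contiguous runs on two distinct chromosomes
  chr_pairs <- utils::combn(spec$n_chromosomes, 2L)
  # blocks are appended as contiguous runs (never splitting a tandem pair)
  for (bi in seq_len(n_blocks)) {
    pr <- chr_pairs[, ((bi - 1L) %% ncol(chr_pairs)) + 1L]
    chrom_genes[[pr[1L]]] <- c(chrom_genes[[pr[1L]]], block_sides[[bi]]$a)
    chrom_genes[[pr[2L]]] <- c(chrom_genes[[pr[2L]]], block_sides[[bi]]$b)
  }

  # linear coordinates with random intergenic gaps
  loci <- list()
  tandem_partner_ids <- vapply(tandem_partners, `[[`, "", "id")
  for (ch in seq_len(spec$n_chromosomes)) {
    pos <- 10000L
    chrom_ids <- chrom_genes[[ch]]
    for (gi in seq_along(chrom_ids)) {
      id <- chrom_ids[gi]
      g <- genes[[id]]
      cds_len <- nchar(g$cds)
      n_ex <- min(g$n_exons, cds_len %/% 60L)
      bounds <- sort(sample(seq_len(cds_len - 1L), n_ex - 1L))
      ex_lens <- diff(c(0L, bounds, cds_len))
      intron_lens <- if (n_ex > 1L) sample(200:2000, n_ex - 1L, TRUE) else integer(0)
      starts <- pos + cumsum(c(0L, utils::head(ex_lens, -1L) + intron_lens))
      ends <- starts + ex_lens - 1L
      strand <- sample(c("+", "-"), 1L)
      loci[[id]] <- gene_locus(
        gene_id = id, chromosome = paste0("chr", ch),
        start = starts[1L], end = ends[n_ex], strand = strand,
        exons = cbind(starts, ends),
        protein_seq = g$protein, cds_seq = g$cds
      )
      # a tandem partner follows its source within the tandem window;
      # all other neighbours sit far beyond it
      next_is_partner <- gi < length(chrom_ids) &&
        chrom_ids[gi + 1L] %in% tandem_partner_ids &&
        identical(genes[[chrom_ids[gi + 1L]]]$partner, id)
      gap <- if (next_is_partner) {
        spec$tandem_separation_bp
      } else {
        sample(120000:200000, 1L)
      }
      pos <- ends[n_ex] + gap
    }
  }
  prot <- proteome(loci, genome_label = sprintf("sim_seed%d", spec$seed))

  truth <- do.call(rbind, lapply(genes[names(loci)], function(g) {
    l <- loci[[g$id]]
    data.frame(gene_id = g$id, chromosome = l$chromosome, start = l$start,
               end = l$end, strand = l$strand, n_exons = nrow(l$exons),
               role = g$role, subfamily = g$fam %||% NA,
               subgroup = g$grp %||% NA,
               divergence = g$divergence %||% NA,
               partner = g$partner %||% NA,
               dup_type = g$dup_type %||% NA,
               block = g$block %||% NA,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      proteome = file.path(out_dir, "proteome.faa"),
      cds = file.path(out_dir, "cds.fna"),
      gff = file.path(out_dir, "genes.gff3"),
      truth = file.path(out_dir, "truth.tsv")
    )
    write_fasta(proteome_seqs(prot, "protein"), files$proteome)
    write_fasta(proteome_seqs(prot, "cds"), files$cds)
    .write_gff3(prot, files$gff)
    write.table(truth, files$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(prot = prot, truth = truth, references = refs, files = files)
}

# minimal GFF3 writer for generator output (gene/mRNA/exon per locus)
.write_gff3 <- function(prot, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (l in prot$loci) {
    base <- sprintf("%s\tmipfam_sim\t%%s\t%%d\t%%d\t.\t%s\t.\t%%s",
                    l$chromosome, l$strand)
    writeLines(sprintf(base, "gene", l$start, l$end,
                       paste0("ID=", l$gene_id)), con)
    mid <- paste0(l$gene_id, ".1")
    writeLines(sprintf(base, "mRNA", l$start, l$end,
                       paste0("ID=", mid, ";Parent=", l$gene_id)), con)
    for (e in seq_len(nrow(l$exons))) {
      writeLines(sprintf(base, "exon", l$exons[e, 1L], l$exons[e, 2L],
                         paste0("ID=", mid, ".exon", e, ";Parent=", mid)),
                 con)
      writeLines(sprintf(base, "CDS", l$exons[e, 1L], l$exons[e, 2L],
                         paste0("ID=", mid, ".cds", e, ";Parent=", mid)),
                 con)
    }
  }
  invisible(path)
}

#' Specification for a diverged codon-sequence pair
#'
#' @param seed RNG seed.
#' @param codons Sequence length in codons.
#' @param target_dn,target_ds Target nonsynonymous and synonymous
#'   substitutions per site. Targets at or above 0.75 are refused as
#'   saturated (beyond reliable Jukes-Cantor recovery).
#' @return List of class `EvolSimSpec`.
#' @export
evol_sim_spec <- function(seed = 1L, codons = 300L, target_dn = 0.1,
                          target_ds = 0.5) {
  if (target_dn >= 0.75 || target_ds >= 0.75) {
    stop("saturation: targets must be below 0.75 substitutions/site")
  }
  if (target_dn < 0 || target_ds < 0) stop("targets must be non-negative")
  structure(list(seed = seed, codons = codons, target_dn = target_dn,
                 target_ds = target_ds), class = "EvolSimSpec")
}

#' Simulate a codon-sequence pair with controlled dN and dS
#'
#' An ancestral CDS is drawn; one copy then receives
#' `round(target * sites)` single-nucleotide substitutions of each class at
#' randomly chosen eligible positions (synonymous changes at synonymous
#' sites, nonsynonymous changes avoiding stop codons), re-evaluating
#' eligibility after every step. The realized per-site rates are returned
#' as truth.
#'
#' @param spec An [evol_sim_spec()].
#' @return List: `cds_a`, `cds_b`, `realized_dn`, `realized_ds`,
#'   `n_syn`, `n_nonsyn`, `S`, `N` (ancestral site counts).
#' @export
simulate_cds_pair <- function(spec = evol_sim_spec()) {
  stopifnot(inherits(spec, "EvolSimSpec"))
  set.seed(spec$seed)
  code <- .genetic_code()
  non_stop <- names(code)[code != "*"]
  anc <- sample(non_stop, spec$codons, TRUE)
  S <- sum(vapply(anc, .syn_sites, 0))
  N <- 3 * spec$codons - S
  n_syn <- round(spec$target_ds * S)
  n_nonsyn <- round(spec$target_dn * N)
  cur <- anc
  # uniform sampling over eligible single-nucleotide changes by rejection:
  # draw a random (codon, position, alternative) triple and accept it when
  # it has the requested synonymy class and creates no stop codon
  apply_changes <- function(cur, n, synonymous) {
    L <- length(cur)
    for (step in seq_len(n)) {
      accepted <- FALSE
      for (try in seq_len(20000L)) {
        ci <- sample.int(L, 1L)
        p <- sample.int(3L, 1L)
        chars <- strsplit(cur[ci], "")[[1L]]
        alt <- sample(setdiff(NUC, chars[p]), 1L)
        mut <- chars; mut[p] <- alt
        mc <- paste(mut, collapse = "")
        if (code[[mc]] == "*") next
        if ((code[[mc]] == code[[cur[ci]]]) != synonymous) next
        cur[ci] <- mc
        accepted <- TRUE
        break
      }
      if (!accepted) stop("saturation: no eligible site found")
    }
    cur
  }
  cur <- apply_changes(cur, n_syn, TRUE)
  cur <- apply_changes(cur, n_nonsyn, FALSE)
  list(cds_a = paste(anc, collapse = ""), cds_b = paste(cur, collapse = ""),
       realized_dn = n_nonsyn / N, realized_ds = n_syn / S,
       n_syn = n_syn, n_nonsyn = n_nonsyn, S = S, N = N)
}

#' Specification for synthetic expression, water and qPCR data
#'
#' Defaults emulate a two-cultivar seed-coat series (outer/inner tissue at
#' three developmental stages, three biological replicates) with three
#' planted water-correlated genes among an aquaporin-sized gene set, plus a
#' PEG-treatment qPCR table with planted fold changes.
#'
#' @param seed RNG seed.
#' @param n_genes Number of genes in the FPKM matrix.
#' @param n_correlated Planted water-correlated genes.
#' @param r_target Target Pearson correlation of planted genes.
#' @param stages Developmental stages (days after pollination).
#' @param cultivars Cultivar labels.
#' @param n_reps Biological replicates per sample point.
#' @param base_fpkm Median background FPKM.
#' @param qpcr_genes Genes in the qPCR table.
#' @param qpcr_conditions Treatment time points (h).
#' @param qpcr_folds Named list (per gene) of planted fold changes per
#'   condition, or `NULL` to draw log2 folds in [-2, 1].
#' @return List of class `ExprSimSpec`.
#' @export
expr_sim_spec <- function(seed = 1L, n_genes = 38L, n_correlated = 3L,
                          r_target = 0.9, stages = c(50L, 95L, 140L),
                          cultivars = c("D", "T"), n_reps = 3L,
                          base_fpkm = 5, qpcr_genes = paste0("G", 1:7),
                          qpcr_conditions = c(0L, 1L, 6L, 12L, 24L),
                          qpcr_folds = NULL) {
  stopifnot(n_correlated <= n_genes, r_target > 0, r_target < 1)
  structure(as.list(environment()), class = "ExprSimSpec")
}

#' Simulate expression, water-accumulation and qPCR inputs
#'
#' FPKM values are negative-binomial draws around planted means. Outer
#' seed-coat water content rises with stage; planted correlated genes track
#' the water series linearly with noise calibrated to the target Pearson r.
#' Ct values encode planted fold changes against a constant reference gene.
#'
#' @param spec An [expr_sim_spec()].
#' @param out_dir Optional directory for `fpkm.tsv`, `water.tsv`, `ct.tsv`,
#'   `truth.tsv`.
#' @return List: `fpkm` (matrix genes x samples), `samples` (metadata),
#'   `water` (per sample FW/DW/percent), `ct` (long qPCR table), `truth`
#'   (planted parameters), `files`.
#' @export
simulate_expression <- function(spec = expr_sim_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "ExprSimSpec"))
  set.seed(spec$seed)
  genes <- paste0("G", seq_len(spec$n_genes))
  samples <- expand.grid(cultivar = spec$cultivars, tissue = c("O", "I"),
                         stage = spec$stages, rep = seq_len(spec$n_reps),
                         stringsAsFactors = FALSE)
  samples$sample_id <- with(samples,
                            paste0(cultivar, tissue, stage, "_r", rep))

  # water series: outer coat accumulates with stage, inner stays lower
  stage_idx <- match(samples$stage, spec$stages)
  wc_mean <- ifelse(samples$tissue == "O", 68 + 8 * stage_idx,
                    55 + 1.5 * stage_idx)
  wc <- pmin(98, pmax(30, wc_mean + rnorm(nrow(samples), 0, 1.5)))
  FW <- 2 + runif(nrow(samples), -0.3, 0.3)
  DW <- FW * (1 - wc / 100)
  water <- data.frame(sample_id = samples$sample_id, FW = FW, DW = DW,
                      percent = water_content(FW, DW),
                      stringsAsFactors = FALSE)

  correlated <- utils::head(genes, spec$n_correlated)
  fpkm <- matrix(0, spec$n_genes, nrow(samples),
                 dimnames = list(genes, samples$sample_id))
  slope_truth <- setNames(numeric(0), character(0))
  for (g in genes) {
    if (g %in% correlated) {
      # expression tracks water with noise tuned to the target r
      beta <- runif(1L, 0.8, 1.6)
      sigma <- beta * sd(wc) * sqrt(1 / spec$r_target^2 - 1)
      expr <- pmax(0.1, 20 + beta * (wc - mean(wc)) + rnorm(length(wc), 0, sigma))
      fpkm[g, ] <- expr
      slope_truth[g] <- beta
    } else {
      mu <- spec$base_fpkm * exp(rnorm(1L, 0, 1))
      fpkm[g, ] <- rnbinom(ncol(fpkm), size = 5, mu = mu * 10) / 10
    }
  }

  # qPCR table with planted folds
  folds <- spec$qpcr_folds
  if (is.null(folds)) {
    folds <- lapply(spec$qpcr_genes, function(g) {
      f <- 2^runif(length(spec$qpcr_conditions) - 1L, -2, 1)
      setNames(c(1, f), spec$qpcr_conditions)
    })
    names(folds) <- spec$qpcr_genes
  }
  ct_rows <- list()
  for (r in seq_len(spec$n_reps)) {
    for (cond in spec$qpcr_conditions) {
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        gene = "actin", condition = cond, replicate = r,
        ct = 20 + rnorm(1L, 0, 0.05), stringsAsFactors = FALSE)
    }
  }
  for (g in spec$qpcr_genes) {
    base_dct <- runif(1L, 2, 6)
    for (cond in spec$qpcr_conditions) {
      target_dct <- base_dct - log2(folds[[g]][[as.character(cond)]])
      for (r in seq_len(spec$n_reps)) {
        ct_rows[[length(ct_rows) + 1L]] <- data.frame(
          gene = g, condition = cond, replicate = r,
          ct = 20 + target_dct + rnorm(1L, 0, 0.05),
          stringsAsFactors = FALSE)
      }
    }
  }
  ct <- do.call(rbind, ct_rows)

  truth <- list(correlated_genes = correlated, slopes = slope_truth,
                r_target = spec$r_target, folds = folds)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(fpkm = file.path(out_dir, "fpkm.tsv"),
                  water = file.path(out_dir, "water.tsv"),
                  ct = file.path(out_dir, "ct.tsv"),
                  truth = file.path(out_dir, "truth.tsv"))
    write.table(data.frame(gene_id = rownames(fpkm), fpkm,
                           check.names = FALSE),
                files$fpkm, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(water, files$water, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(ct, files$ct, sep = "\t", quote = FALSE, row.names = FALSE)
    truth_df <- data.frame(gene = correlated, slope = slope_truth[correlated],
                           r_target = spec$r_target)
    write.table(truth_df, files$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(fpkm = fpkm, samples = samples, water = water, ct = ct,
       truth = truth, files = files)
}
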