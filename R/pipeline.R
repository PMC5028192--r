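#' Resolved run configuration
#'
#' Aggregates the pipeline's tunable settings with their standard defaults:
#' 21-nt interaction heads, 37-nt folding window, 200 shuffles, genome-level
#' alpha 0.05, profile alpha 0.001, window sizes 10 (ncRNA) / 21 (mRNA) with
#' step 1, ACCESS energy mode with a 25-nt site cap. Every `run_*` driver
#' echoes the resolved configuration as `#`-prefixed header lines in its
#' output files so runs are self-describing and diffable.
#'
#' @param ... overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(head_len = 21L, fold_len = 37L, n_shuffles = 200L,
              alpha = 0.05, profile_alpha = 0.001, w_ncrna = 10L,
              w_mrna = 21L, step = 1L, mode = "access", max_site = 25L,
              seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

config_header <- function(cfg) {
  vapply(names(cfg), function(k)
    sprintf("# %s = %s", k, paste(format(cfg[[k]]), collapse = ",")),
    character(1))
}

#' Write a result table with a config echo header
#'
#' @param d data.frame.
#' @param path output TSV path.
#' @param cfg a [run_config()] (optional).
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(d, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) writeLines(config_header(cfg), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_result_tsv <- function(path) {
  read.delim(path, comment.char = "#")
}

#' Pipeline drivers
#'
#' Thin file-based entry points tying the stages together; each reads
#' standard FASTA/TSV inputs, runs the corresponding analysis with a
#' [run_config()], and writes `#`-headed TSV outputs into `out_dir`. The
#' numbered scripts under `analysis/` are narrative wrappers around these.
#'
#' @param mrna_fasta FASTA of mRNA 5' heads (21 nt records).
#' @param ncrna_fasta FASTA of ncRNAs.
#' @param out_dir output directory (created if needed).
#' @param cfg a [run_config()].
#' @param params an [energy_params()] object.
#' @param genome_id genome identifier for single-genome runs.
#' @return the main result object of the stage, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_avoidance_scan <- function(mrna_fasta, ncrna_fasta, out_dir,
                               cfg = run_config(), params = energy_params(),
                               genome_id = "genome") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  heads <- read_fasta(mrna_fasta, role = "MRNA_HEAD")
  ncrnas <- read_fasta(ncrna_fasta, role = "NCRNA")
  bundle <- genome_bundle(genome_id, heads, ncrnas, head_len = cfg$head_len)
  set.seed(cfg$seed)
  res <- avoidance_scan(list(bundle), params, mode = cfg$mode,
                        n_shuffles = cfg$n_shuffles, alpha = cfg$alpha,
                        max_site = cfg$max_site)
  write_result_tsv(res, file.path(out_dir, "avoidance_scan.tsv"), cfg)
  write_result_tsv(phylum_summary(res), file.path(out_dir, "phylum_summary.tsv"), cfg)
  invisible(res)
}

#' @rdname pipeline
#' @param contacts_tsv optional contact table for the accessibility test.
#' @export
run_profile <- function(ncrna_fasta, mrna_fasta, out_dir, cfg = run_config(),
                        params = energy_params(), contacts_tsv = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ncrnas <- read_fasta(ncrna_fasta, role = "NCRNA")
  heads <- read_fasta(mrna_fasta, role = "MRNA_HEAD")
  set.seed(cfg$seed)
  profiles <- lapply(seq_along(ncrnas), function(i) {
    ncrna_window_profile(ncrnas[i], heads, params, w = cfg$w_ncrna,
                         step = cfg$step, n_shuffles = cfg$n_shuffles,
                         alpha = cfg$profile_alpha,
                         reference_id = names(ncrnas)[i])
  })
  tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(reference_id = attr(p, "reference_id"),
               window_start = p$window_start, p = p$p_value,
               avoided = p$avoided)))
  write_result_tsv(tab, file.path(out_dir, "profiles.tsv"), cfg)
  out <- list(profiles = profiles)
  if (!is.null(contacts_tsv)) {
    contacts <- read_contact_table(contacts_tsv)
    assoc <- accessibility_association(profiles[[1]], contacts)
    write_result_tsv(
      data.frame(avoided_contact = assoc$table[1, 1],
                 avoided_accessible = assoc$table[1, 2],
                 other_contact = assoc$table[2, 1],
                 other_accessible = assoc$table[2, 2],
                 odds_ratio = assoc$odds_ratio, p = assoc$p),
      file.path(out_dir, "accessibility.tsv"), cfg)
    out$association <- assoc
  }
  invisible(out)
}

#' @rdname pipeline
#' @param expression_tsv TSV with `gene_id`, `mrna_abundance`,
#'   `protein_abundance` and optional precomputed metric columns.
#' @param cds_fasta FASTA of coding sequences (used to compute metrics when
#'   the expression table lacks them).
#' @export
run_expression <- function(expression_tsv, cds_fasta = NULL,
                           ncrna_fasta = NULL, out_dir, cfg = run_config(),
                           params = energy_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- read.delim(expression_tsv, comment.char = "#")
  need <- setdiff(c("cai", "fold5p", "avoidance"), names(rec))
  if (length(need)) {
    if (is.null(cds_fasta) || is.null(ncrna_fasta)) {
      stop("expression table lacks ", paste(need, collapse = ", "),
           "; provide cds_fasta and ncrna_fasta to compute them")
    }
    cds <- read_fasta(cds_fasta, role = "CDS")
    ncrnas <- read_fasta(ncrna_fasta, role = "NCRNA")
    cds <- cds[rec$gene_id]
    sc <- score_candidates(unname(cds), ncrnas, codon_usage(cds), params,
                           mode = cfg$mode, head_len = cfg$head_len,
                           fold_len = cfg$fold_len)
    rec$cai <- sc$cai; rec$fold5p <- sc$fold5p; rec$avoidance <- sc$avoidance_sum
  }
  keep <- rec$protein_abundance > 0
  lp <- log(rec$protein_abundance[keep])
  cors <- do.call(rbind, lapply(c("cai", "fold5p", "avoidance"), function(m) {
    s <- spearman(rec[[m]][keep], lp)
    data.frame(metric = m, rho = s$rho, p = s$p)
  }))
  vp <- variance_partition(rec)
  write_result_tsv(cors, file.path(out_dir, "correlations.tsv"), cfg)
  write_result_tsv(
    data.frame(model = c(names(vp$r2_single), "full", "full_minus_avoidance"),
               r2 = c(unname(vp$r2_single), vp$r2_full, vp$r2_minus_avoidance)),
    file.path(out_dir, "variance_partition.tsv"), cfg)
  if ("mrna_abundance" %in% names(rec) &&
      nrow(rec) >= 40L) {
    oz <- outlier_zscores(rec)
    write_result_tsv(oz, file.path(out_dir, "outlier_zscores.tsv"), cfg)
  }
  invisible(list(correlations = cors, variance = vp))
}

#' @rdname pipeline
#' @param protein amino-acid string to design constructs for.
#' @param n_samples synonymous variants to sample.
#' @param spec a [design_spec()].
#' @param usage codon usage reference; defaults to usage accumulated over the
#'   sampled pool itself.
#' @export
run_design <- function(protein, ncrna_fasta, out_dir, n_samples = 10000L,
                       spec = design_spec(), cfg = run_config(),
                       params = energy_params(), usage = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ncrnas <- read_fasta(ncrna_fasta, role = "NCRNA")
  set.seed(cfg$seed)
  pool <- sample_synonymous(protein, n_samples)
  if (is.null(usage)) usage <- codon_usage(pool)
  scored <- score_candidates(pool, ncrnas, usage, params,
                             head_len = cfg$head_len, fold_len = cfg$fold_len)
  sel <- select_extremes(scored, spec)
  ids <- sprintf("construct%02d_%s", seq_len(nrow(sel)), sel$category)
  desc <- sprintf("%s cai=%.3f fold5p=%.2f avoidance=%.2f gc=%.3f",
                  ids, sel$cai, sel$fold5p, sel$avoidance_sum, sel$gc)
  write_fasta(setNames(sel$cds, desc), file.path(out_dir, "constructs.fasta"))
  rep <- cbind(id = ids, sel[, c("category", "cai", "fold5p", "avoidance_sum",
                                 "gc", "gc5p")])
  write_result_tsv(rep, file.path(out_dir, "design_report.tsv"), cfg)
  invisible(sel)
}

#' @rdname pipeline
#' @param spec_synth a [synthetic_spec()].
#' @export
run_simulate <- function(spec_synth, out_dir, params = energy_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec_synth$seed)
  for (g in seq_len(spec_synth$n_genomes)) {
    gid <- sprintf("synth%03d", g)
    b <- synth_genome(spec_synth, genome_id = gid, params = params)
    write_fasta(b$mrna_heads, file.path(out_dir, paste0(gid, "_heads.fasta")))
    write_fasta(b$ncrnas, file.path(out_dir, paste0(gid, "_ncrnas.fasta")))
  }
  cfgline <- vapply(names(unclass(spec_synth)), function(k)
    sprintf("%s = %s", k, paste(format(spec_synth[[k]]), collapse = ",")),
    character(1))
  writeLines(c("# synthetic_spec", paste("#", cfgline)),
             file.path(out_dir, "simulation_config.txt"))
  invisible(out_dir)
}
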