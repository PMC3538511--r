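## Tabular output dialects, the SNP map file, the run log, and ingestion
## of external genotype tables.
##
## Both output dialects share the same left columns -- disease status
## (1 = affected, 0 = unaffected), gender (1/2), the causal exposure, then
## any noise exposures -- followed by the genetic columns: two nucleotide
## columns per SNP in the phased dialect, or one 1/2/3 code per SNP in the
## genotype dialect (2 = heterozygote; 3 = high-risk homozygote at a DPL,
## lower-frequency homozygote elsewhere; ties at frequency 0.5 are broken
## lexicographically, treating the alphabetically last allele as minor).

left_columns <- function(pop, rows) {
  df <- data.frame(status = if (is.null(pop$status)) rep(NA_integer_, pop$n)
                   else pop$status,
                   gender = pop$gender)
  df$exposure <- if (is.null(pop$exposure)) rep(NA_real_, pop$n) else
    pop$exposure
  if (!is.null(pop$noise)) df <- cbind(df, pop$noise)
  df[rows, , drop = FALSE]
}

#' Genotype codes for every marker in a population
#'
#' Applies the 1/2/3 coding rule: at a DPL, 3 is the high-risk homozygote;
#' at any other SNP, 3 is the homozygote of the lower-frequency allele
#' (per the panel's declared frequencies); 2 is always the heterozygote.
#'
#' @param pop a `gxe_population`.
#' @return integer matrix, one column per marker.
#' @export
genotype_codes <- function(pop) {
  stopifnot(inherits(pop, "gxe_population"))
  if (!is.null(pop$geno_codes)) return(pop$geno_codes)   # genotypic ingestion
  L <- length(pop$panel$marker_ids)
  codes <- matrix(0L, pop$n, L, dimnames = list(NULL, pop$panel$marker_ids))
  dpl_ids <- c(pop$dpl_a$marker_id, pop$dpl_b$marker_id)
  for (j in seq_len(L)) {
    alt_copies <- pop$h1[, j] + pop$h2[, j]
    id <- pop$panel$marker_ids[j]
    if (id == dpl_ids[1L]) { codes[, j] <- pop$genotype_a; next }
    if (id == dpl_ids[2L]) { codes[, j] <- pop$genotype_b; next }
    qalt <- pop$panel$freq[j]
    minor_is_alt <- if (qalt != 0.5) qalt < 0.5 else
      pop$panel$alleles[2L, j] > pop$panel$alleles[1L, j]
    codes[, j] <- 1L + if (minor_is_alt) alt_copies else 2L - alt_copies
  }
  codes
}

resolve_rows <- function(pop, sample) {
  if (is.null(sample)) return(seq_len(pop$n))
  stopifnot(inherits(sample, "case_control_sample"))
  c(sample$cases, sample$controls)
}

#' Write a population (or case-control sample) in the phased dialect
#'
#' Tab-delimited, one header row; left columns as described in the package
#' overview, then two nucleotide columns per SNP (`<id>_1`, `<id>_2`) in
#' the maternal/paternal order in which the haplotypes were drawn.
#'
#' @param pop a `gxe_population` carrying phased haplotypes.
#' @param path output file path.
#' @param sample optional `case_control_sample` restricting the rows.
#' @return `path`, invisibly.
#' @export
write_phased <- function(pop, path, sample = NULL) {
  stopifnot(inherits(pop, "gxe_population"))
  if (is.null(pop$h1))
    stop_gxe(paste0("population has no phased haplotypes; use ",
                    "write_genotypic() for genotype-coded data"),
             class = "gxesim_validation_error")
  rows <- resolve_rows(pop, sample)
  df <- left_columns(pop, rows)
  L <- length(pop$panel$marker_ids)
  for (j in seq_len(L)) {
    al <- pop$panel$alleles[, j]
    df[[paste0(pop$panel$marker_ids[j], "_1")]] <- al[pop$h1[rows, j] + 1L]
    df[[paste0(pop$panel$marker_ids[j], "_2")]] <- al[pop$h2[rows, j] + 1L]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a population (or case-control sample) in the genotype dialect
#'
#' Same left columns as the phased dialect, then one 1/2/3 code per SNP.
#'
#' @inheritParams write_phased
#' @return `path`, invisibly.
#' @export
write_genotypic <- function(pop, path, sample = NULL) {
  stopifnot(inherits(pop, "gxe_population"))
  rows <- resolve_rows(pop, sample)
  df <- cbind(left_columns(pop, rows),
              as.data.frame(genotype_codes(pop)[rows, , drop = FALSE]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a population table
#'
#' Reads a file written by [write_phased()] or [write_genotypic()] into a
#' data frame (columns as written).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_population_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write the SNP map file
#'
#' One row per SNP: marker id, block (region) index, and 1-based genomic
#' position (strictly increasing within each region).
#'
#' @param panel a `hap_panel` (or the `panel` element of a population).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snp_map <- function(panel, path) {
  df <- data.frame(id = panel$marker_ids, region = panel$block,
                   position = panel$positions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an external genotype table
#'
#' Ingests a whitespace/tab-delimited genotype table, one row per
#' individual, with a header of marker ids.  Two dialects are accepted:
#' `"phased"` (two columns per SNP named `<id>_1`, `<id>_2` holding
#' nucleotide symbols) and `"genotypic"` (one 1/2/3 code column per SNP,
#' taken as-is).  External genotypes are accepted without enforcing
#' Hardy-Weinberg equilibrium or cross-locus independence.
#'
#' @param path file path.
#' @param dialect `"phased"` or `"genotypic"`.
#' @param dpl_a,dpl_b `locus_spec` objects; their marker ids must appear in
#'   the table header (referential integrity).
#' @return a `gxe_population` (genotypes only).
#' @export
read_genotype_table <- function(path, dialect = c("phased", "genotypic"),
                                dpl_a, dpl_b) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dpl_a, "locus_spec"), inherits(dpl_b, "locus_spec"))
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  n <- nrow(df)
  if (n < 1L)
    stop_gxe("genotype table \"%s\" is empty", path,
             class = "gxesim_validation_error")
  if (dialect == "genotypic") {
    ids <- names(df)
    for (spec in list(dpl_a, dpl_b))
      if (!spec$marker_id %in% ids)
        stop_gxe("DPL \"%s\" is not a marker of the genotype table",
                 spec$marker_id, class = "gxesim_validation_error")
    codes <- as.matrix(df)
    storage.mode(codes) <- "integer"
    if (!all(codes %in% 1:3))
      stop_gxe("genotype dialect requires codes 1/2/3 only",
               class = "gxesim_validation_error")
    pop <- structure(list(
      n = n,
      panel = list(n_loci = ncol(codes), marker_ids = ids,
                   block = rep(1L, ncol(codes)),
                   positions = seq_len(ncol(codes)),
                   alleles = NULL, freq = NULL),
      h1 = NULL, h2 = NULL, geno_codes = codes,
      dpl_a = dpl_a, dpl_b = dpl_b,
      genotype_a = codes[, dpl_a$marker_id],
      genotype_b = codes[, dpl_b$marker_id],
      exposure = NULL, noise = NULL,
      gender = 1L + (seq_len(n) %% 2L), status = NULL), # placeholder labels
      class = "gxe_population")
    return(pop)
  }
  nm <- names(df)
  if (length(nm) %% 2L != 0L || !all(grepl("_[12]$", nm)))
    stop_gxe("phased dialect requires two columns per SNP named <id>_1, <id>_2",
             class = "gxesim_validation_error")
  ids <- unique(sub("_[12]$", "", nm))
  L <- length(ids)
  h1 <- matrix(0L, n, L); h2 <- matrix(0L, n, L)
  alleles <- matrix("", 2L, L); freq <- numeric(L)
  for (j in seq_len(L)) {
    a1 <- as.character(df[[paste0(ids[j], "_1")]])
    a2 <- as.character(df[[paste0(ids[j], "_2")]])
    obs <- sort(unique(c(a1, a2)))
    if (length(obs) > 2L)
      stop_gxe("marker %s has more than two alleles", ids[j],
               class = "gxesim_validation_error")
    ref <- obs[1L]; alt <- if (length(obs) == 2L) obs[2L] else obs[1L]
    alleles[, j] <- c(ref, alt)
    h1[, j] <- as.integer(a1 == alt & length(obs) == 2L)
    h2[, j] <- as.integer(a2 == alt & length(obs) == 2L)
    freq[j] <- mean(c(h1[, j], h2[, j]))
  }
  risk_code <- function(spec) {
    j <- match(spec$marker_id, ids)
    if (is.na(j))
      stop_gxe("DPL \"%s\" is not a marker of the genotype table",
               spec$marker_id, class = "gxesim_validation_error")
    if (!spec$high_risk_allele %in% alleles[, j])
      stop_gxe("high-risk allele %s not observed at marker %s",
               spec$high_risk_allele, spec$marker_id,
               class = "gxesim_validation_error")
    alt_copies <- h1[, j] + h2[, j]
    if (alleles[2L, j] == spec$high_risk_allele) 1L + alt_copies
    else 3L - alt_copies
  }
  structure(list(
    n = n,
    panel = list(n_loci = L, marker_ids = ids, block = rep(1L, L),
                 positions = seq_len(L), alleles = alleles, freq = freq),
    h1 = h1, h2 = h2, dpl_a = dpl_a, dpl_b = dpl_b,
    genotype_a = risk_code(dpl_a), genotype_b = risk_code(dpl_b),
    exposure = NULL, noise = NULL,
    gender = 1L + (seq_len(n) %% 2L), status = NULL),
    class = "gxe_population")
}

fmt_matrix <- function(m, digits = 10) {
  apply(format(round(m, digits), trim = TRUE, scientific = FALSE), 1L,
        paste, collapse = "\t")
}

#' Write the run log
#'
#' An extensive plain-text report of every intermediate step of a run: the
#' configuration echo, derived sub-seeds, genotype frequencies, marginal
#' risks, the independent and deformed penetrance matrices, the increment
#' matrix, the logistic coefficient tables, the prevalence residual, and
#' per-stage timings.  Timestamp and timing lines are prefixed with `#` so
#' two runs with identical configuration and seed produce logs that are
#' identical apart from `#` lines.
#'
#' @param run a `gxe_run` from [simulate_population()], or the list
#'   returned by [parameterize()] together with a `config` element.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(run, path) {
  art <- if (!is.null(run$artifacts)) run$artifacts else run
  config <- run$config
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("== run log ==")
  w("# generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  w("")
  w("== configuration ==")
  w("prevalence\t%.10g", config$prevalence)
  for (side in c("dpl_a", "dpl_b")) {
    s <- config[[side]]
    w("%s\t%s\thigh_risk=%s\tfreq=%.10g\trr=%.10g\tw=%.10g",
      side, s$marker_id, s$high_risk_allele, s$allele_freq, s$rr, s$w)
  }
  w("environment\tmean=%.10g\tsd=%.10g\tor_per_unit=%.10g",
    config$env$mean, config$env$sd, config$env$or_per_unit)
  w("gxe_model\t%s", config$gxe_model)
  if (nrow(config$epistasis)) {
    for (i in seq_len(nrow(config$epistasis)))
      w("epistasis\tcell=(%d,%d)\tpercent=%.10g", config$epistasis$row[i],
        config$epistasis$col[i], config$epistasis$percent[i])
  } else w("epistasis\tnone")
  w("n_individuals\t%d", config$n_individuals)
  w("seed\t%d", config$seed)
  if (!is.null(run$seeds)) {
    w("")
    w("== derived sub-seeds ==")
    for (nm in names(run$seeds)) w("%s\t%d", nm, run$seeds[[nm]])
  }
  w("")
  w("== genotype frequencies ==")
  w("locus_a\t%s", paste(sprintf("%.10g", art$freqs_a), collapse = "\t"))
  w("locus_b\t%s", paste(sprintf("%.10g", art$freqs_b), collapse = "\t"))
  w("")
  w("== marginal genotype risks ==")
  w("locus_a\t%s", paste(sprintf("%.10g", art$marginal$tr_a), collapse = "\t"))
  w("locus_b\t%s", paste(sprintf("%.10g", art$marginal$tr_b), collapse = "\t"))
  w("")
  w("== independent penetrance matrix TR_I ==")
  writeLines(fmt_matrix(art$tr_independent$tr), con)
  w("")
  w("== epistatic increment matrix Delta ==")
  writeLines(fmt_matrix(art$delta$delta), con)
  w("")
  w("== deformed penetrance matrix TR_E ==")
  writeLines(fmt_matrix(art$tr_epistatic$tr), con)
  w("epistatic_ratio_3_3\t%.10g",
    art$tr_epistatic$tr[3, 3] / art$tr_independent$tr[3, 3])
  w("")
  w("== logistic coefficients (model %s) ==", art$coefficients$model)
  w("beta_ab\t%.10g\tanchor_cell\t(%d,%d)", art$coefficients$beta_ab,
    art$coefficients$anchor[1], art$coefficients$anchor[2])
  w("alpha:")
  writeLines(fmt_matrix(art$coefficients$alpha), con)
  w("beta:")
  writeLines(fmt_matrix(art$coefficients$beta), con)
  w("")
  w("== prevalence check ==")
  w("implied\t%.12g", art$prevalence_check$implied)
  w("designed\t%.12g", art$prevalence_check$designed)
  w("residual\t%.3e", art$prevalence_check$residual)
  w("pass\t%s", art$prevalence_check$pass)
  if (!is.null(run$timings)) {
    w("")
    w("== timings (seconds) ==")
    for (nm in names(run$timings)) w("# %s\t%.3f", nm, run$timings[[nm]])
  }
  invisible(path)
}
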