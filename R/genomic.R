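#' A genomic cohort record
#'
#' One data owner's record: SNP genotypes (two alleles per biallelic
#' site), phenotype labels, gender and ethnicity. These are the four
#' keyword categories the encrypted index supports.
#'
#' @param owner_id Non-empty owner ID string.
#' @param snps Named character vector, `rsID -> genotype`, each genotype
#'   exactly two characters from `A`, `C`, `G`, `T`.
#' @param phenotypes Character vector of phenotype labels (may be empty).
#' @param gender,ethnicity Single strings.
#' @return An object of class `genomic_record`.
#' @examples
#' r <- genomic_record("PGP001", c(rs4988235 = "CT"), "lactose_intolerance",
#'                     "female", "european")
#' encode_record(r)$keywords
#' @export
genomic_record <- function(owner_id, snps = character(0),
                           phenotypes = character(0),
                           gender = NA_character_,
                           ethnicity = NA_character_) {
  if (!is.character(owner_id) || length(owner_id) != 1L ||
      nchar(owner_id) == 0L)
    rdb_stop("owner_id must be a non-empty string", "validation")
  snps <- snps[!is.na(snps) & nzchar(snps)]
  if (length(snps) > 0L) {
    if (is.null(names(snps)) || any(!nzchar(names(snps))))
      rdb_stop("snps must be named by rsID", "validation")
    bad <- !grepl("^[ACGT]{2}$", snps)
    if (any(bad))
      rdb_stop(paste0("invalid genotype(s): ",
                      paste(unique(snps[bad]), collapse = ", ")),
               "validation")
  }
  structure(list(owner_id = owner_id, snps = snps,
                 phenotypes = as.character(phenotypes),
                 gender = gender, ethnicity = ethnicity),
            class = "genomic_record")
}

#' @export
print.genomic_record <- function(x, ...) {
  cat(sprintf("genomic record '%s': %d SNPs, %d phenotypes\n",
              x$owner_id, length(x$snps), length(x$phenotypes)))
  invisible(x)
}

#' Encode a record as a keyword set
#'
#' Each piece of information becomes one canonical, prefix-tagged keyword:
#' `snp:<rsID>=<genotype>` (alleles sorted, so `AG` and `GA` are the same
#' unordered genotype), `pheno:<label>`, `gender:<value>`,
#' `eth:<value>`. Prefixes keep the categories collision-free even if,
#' say, a phenotype label looks like an rsID.
#'
#' @param rec A `genomic_record`.
#' @return List with `id` and the character vector `keywords` of size
#'   `n_snps + n_phenotypes + 2` (gender and ethnicity, when present).
#' @export
encode_record <- function(rec) {
  stopifnot(inherits(rec, "genomic_record"))
  geno <- vapply(rec$snps, function(g) {
    paste(sort(strsplit(g, "")[[1]]), collapse = "")
  }, "")
  kws <- c(
    if (length(rec$snps) > 0L)
      sprintf("snp:%s=%s", names(rec$snps), geno),
    if (length(rec$phenotypes) > 0L)
      sprintf("pheno:%s", sort(rec$phenotypes)),
    if (!is.na(rec$gender)) sprintf("gender:%s", rec$gender),
    if (!is.na(rec$ethnicity)) sprintf("eth:%s", rec$ethnicity)
  )
  list(id = rec$owner_id, keywords = unname(kws))
}

#' Read a cohort table
#'
#' Tab-separated cohort file: header columns `id`, `gender`, `ethnicity`,
#' `phenotypes` (semicolon-separated list), then one column per rsID.
#' Empty genotype cells mean the SNP was not typed for that owner and
#' produce no keyword.
#'
#' @param path Path to the TSV file.
#' @return List of `genomic_record` objects.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  req <- c("id", "gender", "ethnicity", "phenotypes")
  if (!all(req %in% names(df)))
    rdb_stop(paste0("cohort header must contain columns: ",
                    paste(req, collapse = ", ")), "parse")
  if (anyDuplicated(df$id))
    rdb_stop(paste0("duplicate owner id at data line ",
                    which(duplicated(df$id))[1]), "parse")
  rsids <- setdiff(names(df), req)
  lapply(seq_len(nrow(df)), function(i) {
    snps <- stats::setNames(as.character(df[i, rsids]), rsids)
    phen <- strsplit(df$phenotypes[i], ";", fixed = TRUE)[[1]]
    phen <- phen[nzchar(phen)]
    tryCatch(
      genomic_record(df$id[i], snps = snps, phenotypes = phen,
                     gender = df$gender[i], ethnicity = df$ethnicity[i]),
      rdb_validation = function(e)
        rdb_stop(sprintf("data line %d: %s", i, conditionMessage(e)),
                 "parse"))
  })
}

#' @rdname read_cohort
#' @param records List of `genomic_record`s sharing one SNP panel.
#' @export
write_cohort <- function(records, path) {
  rsids <- sort(unique(unlist(lapply(records, function(r) names(r$snps)))))
  rows <- vapply(records, function(r) {
    paste(c(r$owner_id,
            if (is.na(r$gender)) "" else r$gender,
            if (is.na(r$ethnicity)) "" else r$ethnicity,
            paste(r$phenotypes, collapse = ";"),
            vapply(rsids, function(s) {
              g <- r$snps[s]
              if (is.na(g)) "" else unname(g)
            }, "")),
          collapse = "\t")
  }, "")
  writeLines(c(paste(c("id", "gender", "ethnicity", "phenotypes", rsids),
                     collapse = "\t"), rows), path)
  invisible(path)
}

#' Minimal single-sample VCF reader
#'
#' Convenience ingestion of SNP genotypes from an uncompressed
#' single-sample VCF: only the `GT` field of biallelic SNP sites is
#' interpreted; the rsID comes from the `ID` column. Sites with missing
#' calls (`./.`) or without an rsID are skipped. Phenotype, gender and
#' ethnicity are not part of VCF and must be supplied separately.
#'
#' @param path Path to the VCF file.
#' @param owner_id Owner ID for the resulting record.
#' @inheritParams genomic_record
#' @return A `genomic_record`.
#' @export
read_vcf_record <- function(path, owner_id, phenotypes = character(0),
                            gender = NA_character_,
                            ethnicity = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  snps <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L) rdb_stop("VCF line has no sample column", "parse")
    rsid <- f[3]; ref <- f[4]; alt <- f[5]
    if (rsid == "." || nchar(ref) != 1L || nchar(alt) != 1L) next
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gti <- match("GT", fmt)
    if (is.na(gti)) next
    gt <- strsplit(f[10], ":", fixed = TRUE)[[1]][gti]
    al <- strsplit(gt, "[/|]")[[1]]
    if (length(al) != 2L || any(al == ".")) next
    allele <- function(a) if (a == "0") ref else alt
    snps[rsid] <- paste0(allele(al[1]), allele(al[2]))
  }
  genomic_record(owner_id, snps = snps, phenotypes = phenotypes,
                 gender = gender, ethnicity = ethnicity)
}

#' Generate a synthetic cohort
#'
#' Emulates the shape of a real genotyped cohort so the scheme can be
#' exercised with no data download: a biallelic SNP panel is drawn
#' (distinct allele pairs per site), each owner receives a genotype per
#' SNP from the site's three genotype states (allele frequency drawn per
#' site), carries each phenotype independently with the configured
#' prevalence, and gets a gender and an ethnicity from small vocabularies.
#' Defaults give about 25 keywords per owner (20 SNPs + ~3 phenotypes +
#' 2), matching the keyword load used throughout the package's own
#' studies; the cohort size of interest is 69 owners, the size of the
#' public genome-project cohort the scheme was evaluated on.
#'
#' @param n_owners Number of data owners.
#' @param n_snps SNP panel size.
#' @param n_phenotypes Phenotype vocabulary size.
#' @param phenotype_prevalence Per-phenotype carrier probability.
#' @param ethnicities,genders Category vocabularies.
#' @param seed Integer seed; cohorts are reproducible given the seed.
#' @return List of `genomic_record` objects.
#' @export
generate_synthetic_cohort <- function(n_owners = 69, n_snps = 20,
                                      n_phenotypes = 10,
                                      phenotype_prevalence = 0.3,
                                      ethnicities = c("european", "african",
                                                      "east_asian",
                                                      "south_asian",
                                                      "admixed"),
                                      genders = c("female", "male"),
                                      seed) {
  stopifnot(n_owners >= 1, n_snps >= 1, n_phenotypes >= 0)
  rng <- rng_new(seed)
  alleles <- c("A", "C", "G", "T")
  panel <- lapply(seq_len(n_snps), function(i) {
    pair <- alleles[rng_shuffle(rng, 1:4)[1:2]]
    list(rsid = sprintf("rs%07d", 1000000 + i * 1000 + rng_int(rng, 999)),
         ref = pair[1], alt = pair[2],
         maf = rng_int(rng, 40) / 100)  # minor-allele frequency 0.01-0.40
  })
  phen_vocab <- sprintf("phen%02d", seq_len(n_phenotypes))
  draw_allele <- function(site)
    if (rng_int(rng, 100) <= site$maf * 100) site$alt else site$ref
  lapply(seq_len(n_owners), function(i) {
    snps <- vapply(panel, function(site)
      paste0(draw_allele(site), draw_allele(site)), "")
    names(snps) <- vapply(panel, `[[`, "", "rsid")
    carry <- vapply(phen_vocab, function(ph)
      rng_int(rng, 100) <= phenotype_prevalence * 100, logical(1))
    genomic_record(sprintf("PGP%04d", i), snps = snps,
                   phenotypes = phen_vocab[carry],
                   gender = genders[rng_int(rng, length(genders))],
                   ethnicity = ethnicities[rng_int(rng, length(ethnicities))])
  })
}

#' All keywords occurring in a cohort
#' @param cohort List of `genomic_record`s.
#' @return Sorted character vector of distinct keywords.
#' @export
cohort_vocabulary <- function(cohort) {
  sort(unique(unlist(lapply(cohort, function(r) encode_record(r)$keywords))))
}

#' Total number of (ID, keyword) pairs a cohort produces
#' @inheritParams cohort_vocabulary
#' @export
cohort_pair_count <- function(cohort) {
  sum(vapply(cohort, function(r) length(encode_record(r)$keywords), 0L))
}
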