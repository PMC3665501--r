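#' Read PLINK text genotype data (.ped/.map)
#'
#' Parses the PLINK 1 text format.  Phenotype coding follows PLINK: 1 =
#' control, 2 = case; samples with phenotype 0 or -9 are dropped with a
#' warning.  An allele code of 0 marks a missing call.  Genotype codes in
#' the result count the minor allele, with minor status computed from the
#' allele frequencies of the retained samples (ties resolve to the first
#' allele encountered in the file).
#'
#' @param ped_path path to the .ped file (6 leading columns, then two allele
#'   columns per SNP).
#' @param map_path path to the .map file (3 or 4 whitespace-separated
#'   columns: chromosome, SNP id, optional genetic distance, position).
#' @return A [genotype_data] object.
#' @seealso [read_plink_binary()]
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!ncol(map) %in% c(3L, 4L)) {
    stop("malformed .map file: expected 3 or 4 columns, got ", ncol(map))
  }
  m <- nrow(map)
  pos_col <- if (ncol(map) == 4L) 4L else 3L
  snp_ids <- map[[2L]]
  chrs <- map[[1L]]
  poss <- suppressWarnings(as.integer(map[[pos_col]]))

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != want) {
      if ((length(toks[[i]]) - 6L) %% 2L == 0L) {
        stop("SNP count mismatch: .ped line ", i, " carries ",
             (length(toks[[i]]) - 6L) / 2L, " SNPs but .map lists ", m)
      }
      stop("malformed .ped line ", i, ": expected ", want,
           " fields, got ", length(toks[[i]]))
    }
  }
  ped <- do.call(rbind, toks)
  pheno_raw <- ped[, 6L]
  keep <- pheno_raw %in% c("1", "2")
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) dropped: phenotype not case/control")
  }
  ped <- ped[keep, , drop = FALSE]
  if (nrow(ped) == 0L) stop("no case/control samples in .ped")
  phenotype <- as.integer(ped[, 6L] == "2")
  sample_ids <- ped[, 2L]

  geno <- matrix(NA_integer_, nrow = m, ncol = nrow(ped))
  a1v <- a2v <- character(m)
  for (j in seq_len(m)) {
    al1 <- ped[, 5L + 2L * j]
    al2 <- ped[, 6L + 2L * j]
    miss <- al1 == "0" | al2 == "0"
    obs <- c(al1[!miss], al2[!miss])
    lev <- unique(obs)
    if (length(lev) > 2L) {
      stop("malformed .ped: SNP ", snp_ids[j], " has more than two alleles")
    }
    if (length(lev) == 0L) {      # all calls missing
      a1v[j] <- a2v[j] <- "0"
      next
    }
    first <- lev[1L]
    other <- if (length(lev) == 2L) lev[2L] else NA_character_
    f_first <- mean(obs == first)
    if (f_first <= 0.5 || is.na(other)) {
      minor <- first; major <- other
      if (is.na(other)) { minor <- NA_character_; major <- first }
    } else {
      minor <- other; major <- first
    }
    if (is.na(minor)) {            # monomorphic: zero copies of the (absent) minor
      geno[j, !miss] <- 0L
      a1v[j] <- "0"; a2v[j] <- major
    } else {
      geno[j, !miss] <- (al1[!miss] == minor) + (al2[!miss] == minor)
      a1v[j] <- minor; a2v[j] <- major
    }
  }
  meta <- tibble::tibble(snp_id = snp_ids, chr = chrs,
                         pos = poss, a1 = a1v, a2 = a2v)
  genotype_data(geno, phenotype, snp_meta = meta, sample_ids = sample_ids)
}

#' Read PLINK 1 binary genotype data (.bed/.bim/.fam)
#'
#' Decodes SNP-major PLINK 1 .bed files (magic bytes `0x6c 0x1b`, mode byte
#' `0x01`; two bits per call: `00` = homozygous A1, `01` = missing, `10` =
#' heterozygous, `11` = homozygous A2).  Semantics match
#' [read_plink_text()] on an equivalent dataset: codes count the
#' data-derived minor allele and samples without a case/control phenotype
#' are dropped with a warning.
#'
#' @param bed_path,bim_path,fam_path paths to the three PLINK binary files.
#' @return A [genotype_data] object.
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(bim) != 6L) stop("malformed .bim: expected 6 columns")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(fam) != 6L) stop("malformed .fam: expected 6 columns")
  m <- nrow(bim)
  n_all <- nrow(fam)

  bed <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(bed) < 3L || bed[1L] != as.raw(0x6c) || bed[2L] != as.raw(0x1b)) {
    stop("not a PLINK .bed file (bad magic bytes)")
  }
  if (bed[3L] != as.raw(0x01)) {
    stop("unsupported .bed mode byte (need SNP-major 0x01)")
  }
  bps <- ceiling(n_all / 4)
  if (length(bed) - 3L != bps * m) {
    stop("truncated or oversized .bed: expected ", bps * m,
         " data bytes, found ", length(bed) - 3L)
  }
  bits <- as.integer(rawToBits(bed[-(1:3)]))     # little-endian bit pairs
  dim(bits) <- c(2L, 4L * bps, m)
  code2bit <- bits[1L, , , drop = TRUE] + 2L * bits[2L, , , drop = TRUE]
  code2bit <- matrix(code2bit, nrow = 4L * bps, ncol = m)[seq_len(n_all), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  decode <- c(2L, NA_integer_, 1L, 0L)
  geno_all <- matrix(decode[code2bit + 1L], nrow = n_all, ncol = m)

  pheno_raw <- fam[[6L]]
  keep <- pheno_raw %in% c("1", "2")
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) dropped: phenotype not case/control")
  }
  if (!any(keep)) stop("no case/control samples in .fam")
  geno <- t(geno_all[keep, , drop = FALSE])      # SNPs x samples, counts of A1
  phenotype <- as.integer(pheno_raw[keep] == "2")

  a1 <- bim[[5L]]; a2 <- bim[[6L]]
  for (j in seq_len(m)) {                        # orient to the minor allele
    g <- geno[j, ]
    nn <- sum(!is.na(g))
    if (nn == 0L) next
    f1 <- sum(g, na.rm = TRUE) / (2 * nn)
    if (f1 > 0.5) {
      geno[j, ] <- 2L - g
      tmp <- a1[j]; a1[j] <- a2[j]; a2[j] <- tmp
    }
  }
  meta <- tibble::tibble(snp_id = bim[[2L]], chr = bim[[1L]],
                         pos = suppressWarnings(as.integer(bim[[4L]])),
                         a1 = a1, a2 = a2)
  genotype_data(geno, phenotype, snp_meta = meta, sample_ids = fam[[2L]][keep])
}

#' Write genotype data as PLINK 1 binary files
#'
#' Writes `<prefix>.bed` (SNP-major), `<prefix>.bim` and `<prefix>.fam`.
#' Stored A1 is the counted allele, so reading the files back with
#' [read_plink_binary()] reproduces the codes exactly whenever the counted
#' allele is the data-minor allele (the package's orientation convention).
#'
#' @param data a [genotype_data] object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_binary <- function(data, prefix) {
  stopifnot(inherits(data, "genotype_data"))
  g <- data$genotypes
  m <- nrow(g); n <- ncol(g)
  # code -> 2-bit: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  enc <- c(3L, 2L, 0L)
  pad <- 4L * ceiling(n / 4) - n
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    v <- g[j, ]
    tb <- ifelse(is.na(v), 1L, enc[v + 1L])
    if (pad > 0L) tb <- c(tb, rep(0L, pad))
    q <- matrix(tb, nrow = 4L)
    bytes <- q[1L, ] + 4L * q[2L, ] + 16L * q[3L, ] + 64L * q[4L, ]
    writeBin(as.raw(bytes), con)
  }
  meta <- data$snp_meta
  bim <- data.frame(meta$chr, meta$snp_id, 0L, meta$pos, meta$a1, meta$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(data$sample_ids, data$sample_ids, 0L, 0L, 0L,
                    data$phenotype + 1L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write genotype data as PLINK text files (.ped/.map)
#'
#' @inheritParams write_plink_binary
#' @return `prefix`, invisibly.
#' @export
write_plink_text <- function(data, prefix) {
  stopifnot(inherits(data, "genotype_data"))
  g <- data$genotypes
  m <- nrow(g); n <- ncol(g)
  meta <- data$snp_meta
  a1 <- ifelse(is.na(meta$a1) | meta$a1 == "0", "A", meta$a1)
  a2 <- ifelse(is.na(meta$a2) | meta$a2 == "0", "B", meta$a2)
  rows <- character(n)
  for (s in seq_len(n)) {
    v <- g[, s]
    al <- character(2L * m)
    for (j in seq_len(m)) {
      pair <- if (is.na(v[j])) c("0", "0")
      else switch(v[j] + 1L, c(a2[j], a2[j]), c(a1[j], a2[j]), c(a1[j], a1[j]))
      al[c(2L * j - 1L, 2L * j)] <- pair
    }
    rows[s] <- paste(c(data$sample_ids[s], data$sample_ids[s], "0", "0", "0",
                       data$phenotype[s] + 1L, al), collapse = " ")
  }
  writeLines(rows, paste0(prefix, ".ped"))
  map <- data.frame(meta$chr, meta$snp_id, 0L, meta$pos)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write pair-scan records to a TSV file
#'
#' Writes a tab-separated file with a header row, one row per SNP pair,
#' floating scores at 6 significant digits, rows in descending order of the
#' primary score with ties broken by `(snp1_idx, snp2_idx)`.
#'
#' @param records tibble of pair records (e.g. one element of a
#'   [scan_pairs()] result or the output of [gss_stage()]).
#' @param path output file path.
#' @param score name of the primary score column; defaults to the first of
#'   `flt_gss`, `flt_dss`, `flt_ss`, `chi2_neg_log10p` present.
#' @return `path`, invisibly.
#' @export
write_pair_records <- function(records, path, score = NULL) {
  records <- tibble::as_tibble(records)
  if (is.null(score)) {
    score <- intersect(c("flt_gss", "flt_dss", "flt_ss", "chi2_neg_log10p"),
                       names(records))[1]
    if (is.na(score)) score <- NULL
  }
  if (nrow(records) > 0L && !is.null(score)) {
    ord <- order(-records[[score]], records$snp1_idx, records$snp2_idx)
    records <- records[ord, , drop = FALSE]
  }
  isnum <- vapply(records, is.double, logical(1))
  records[isnum] <- lapply(records[isnum], function(x)
    ifelse(is.na(x), NA_character_,
           trimws(formatC(x, digits = 6, format = "g"))))
  out <- file(path, "w")
  on.exit(close(out))
  ok <- tryCatch({
    writeLines(paste(names(records), collapse = "\t"), out)
    if (nrow(records) > 0L) {
      body <- do.call(paste, c(lapply(records, as.character), sep = "\t"))
      writeLines(body, out)
    }
    TRUE
  }, error = function(e) stop("cannot write pair records to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
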