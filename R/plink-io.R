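#' Write genotypes as PLINK PED/MAP text files
#'
#' Markers only (QTL are never exported). Alleles are coded 1/2; a
#' missing genotype becomes `0 0`. MAP positions carry the genetic
#' position in centimorgans and a physical position at 1 cM per Mb.
#'
#' @param prefix output path prefix (`prefix.ped`, `prefix.map`).
#' @param genotypes dosage matrix animals x markers (0/1/2/NA), rows
#'   named by animal id.
#' @param map a `genome_map` (marker rows are used) or a data frame with
#'   `chrom` and `pos_cM` per marker column.
#' @param ped optional pedigree data frame (`id`, `sire`, `dam`, `sex`)
#'   supplying the PED family columns.
#' @param family family id written in column 1.
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(prefix, genotypes, map, ped = NULL, family = "FAM1") {
  mk <- if (inherits(map, "genome_map")) map$loci[map$marker_idx, ] else map
  stopifnot(nrow(mk) == ncol(genotypes))
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- seq_len(nrow(genotypes))

  snp_ids <- sprintf("snp%d_%d", mk$chrom, seq_len(nrow(mk)))
  map_df <- data.frame(chrom = mk$chrom, id = snp_ids,
                       cM = mk$pos_cM, bp = round(mk$pos_cM * 1e6))
  write.table(map_df, paste0(prefix, ".map"), quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")

  sire <- dam <- rep(0L, length(ids))
  sexc <- rep(0L, length(ids))
  if (!is.null(ped)) {
    i <- match(ids, ped$id)
    sire <- ifelse(is.na(i), 0L, ped$sire[i])
    dam <- ifelse(is.na(i), 0L, ped$dam[i])
    sexc <- ifelse(is.na(i), 0L, ifelse(ped$sex[i] == "M", 1L, 2L))
  }
  # dosage -> two allele columns: 0 -> 1 1, 1 -> 1 2, 2 -> 2 2, NA -> 0 0
  a1 <- matrix("1", nrow(genotypes), ncol(genotypes))
  a2 <- matrix("1", nrow(genotypes), ncol(genotypes))
  a1[genotypes == 2] <- "2"
  a2[genotypes >= 1] <- "2"
  a1[is.na(genotypes)] <- "0"
  a2[is.na(genotypes)] <- "0"
  inter <- matrix("", nrow(genotypes), 2L * ncol(genotypes))
  inter[, seq(1, ncol(inter), 2)] <- a1
  inter[, seq(2, ncol(inter), 2)] <- a2
  lines <- paste(family, ids, sire, dam, sexc, -9,
                 apply(inter, 1, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read PLINK PED/MAP text files
#'
#' @param prefix path prefix of `prefix.ped` / `prefix.map`.
#' @return list with `genotypes` (dosage matrix, counted allele "2"),
#'   `map` (chrom, id, cM, bp), and `fam` (family, id, sire, dam, sex).
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chrom", "id", "cM", "bp"))
  lines <- readLines(paste0(prefix, ".ped"))
  parts <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  geno <- matrix(NA_real_, length(parts), m)
  fam <- data.frame(family = character(length(parts)),
                    id = character(length(parts)),
                    sire = character(length(parts)),
                    dam = character(length(parts)),
                    sex = integer(length(parts)))
  for (i in seq_along(parts)) {
    v <- parts[[i]]
    if (length(v) != 6 + 2 * m) stop("malformed PED line ", i)
    fam[i, ] <- list(v[1], v[2], v[3], v[4], as.integer(v[5]))
    al <- matrix(v[-(1:6)], ncol = 2, byrow = TRUE)
    miss <- al[, 1] == "0" | al[, 2] == "0"
    d <- (al[, 1] == "2") + (al[, 2] == "2")
    d[miss] <- NA_real_
    geno[i, ] <- d
  }
  rownames(geno) <- fam$id
  colnames(geno) <- map$id
  list(genotypes = geno, map = map, fam = fam)
}

#' Write a pedigree as CSV
#'
#' Columns: id, sire, dam, sex, generation.
#' @param ped pedigree data frame.
#' @param path output file.
#' @export
write_pedigree_csv <- function(ped, path) {
  utils::write.csv(ped[, intersect(c("id", "sire", "dam", "sex", "gen", "phase"),
                                   names(ped))],
                   path, row.names = FALSE, quote = FALSE)
}

#' Write phenotype records as CSV
#'
#' Columns: id, phenotype, TBV (and EBV when present).
#' @param records records data frame from a simulated population.
#' @param path output file.
#' @export
write_phenotypes_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
}
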