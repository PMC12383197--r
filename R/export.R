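#' Serialize a trait model as CSV
#'
#' One row per QTL: index, chromosome, map position and additive
#' effect. The variance components and mean are repeated as constant
#' columns so the file is self-contained.
#'
#' @param trait_model a `trait_model`.
#' @param map the `genome_map` the model was drawn on.
#' @param path output CSV path.
#' @return invisibly, the written data frame.
#' @export
write_trait_model_csv <- function(trait_model, map, path) {
  q <- map$loci[map$qtl_idx, ]
  stopifnot(nrow(q) == length(trait_model$qtl_effects))
  d <- data.frame(qtl = seq_len(nrow(q)), chrom = q$chrom,
                  pos_cM = q$pos_cM, effect = trait_model$qtl_effects,
                  sigma_a2 = trait_model$sigma_a2,
                  sigma_e2 = trait_model$sigma_e2, mu = trait_model$mu)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(d)
}

#' Export a relationship matrix as text
#'
#' Either a dense CSV (row names = animal ids) or a symmetric triplet
#' file (`i j value`, upper triangle including the diagonal, ids
#' resolved through an index file written alongside as
#' `<path>.index`).
#'
#' @param M symmetric relationship matrix with animal dimnames.
#' @param path output path.
#' @param format `"dense"` or `"triplet"`.
#' @return invisibly, the main output path.
#' @export
write_relationship_matrix <- function(M, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  M <- as.matrix(M)
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(M)))
  if (format == "dense") {
    utils::write.csv(data.frame(id = ids, M, check.names = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    ut <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
    d <- data.frame(i = ut[, 1], j = ut[, 2], value = M[ut])
    utils::write.table(d, path, row.names = FALSE, quote = FALSE)
    writeLines(ids, paste0(path, ".index"))
  }
  invisible(path)
}

#' Read back a relationship matrix written by [write_relationship_matrix()]
#'
#' @param path path given at write time.
#' @param format `"dense"` or `"triplet"`.
#' @return dense symmetric matrix with animal dimnames.
#' @export
read_relationship_matrix <- function(path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    d <- utils::read.csv(path, check.names = FALSE)
    M <- as.matrix(d[, -1, drop = FALSE])
    dimnames(M) <- list(d$id, colnames(d)[-1])
    return(M)
  }
  d <- utils::read.table(path, header = TRUE)
  ids <- readLines(paste0(path, ".index"))
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  M[cbind(d$i, d$j)] <- d$value
  M[cbind(d$j, d$i)] <- d$value
  M
}
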