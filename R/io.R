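# File interfaces: trajectory TSV, popoolation2-style sync, YAML config.

#' Read / write trajectory tables as TSV
#'
#' Columns: line, treatment, generation, locus_id, block_id, alt_count,
#' coverage, pool_n, freq.
#' @param traj an `er_trajectories`
#' @param path file path
#' @export
write_trajectories_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "er_trajectories"))
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_tsv
#' @export
read_trajectories_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$treatment <- as.logical(df$treatment)
  new_trajectories(df)
}

#' Write trajectories in popoolation2 sync format
#'
#' One row per locus (`chromosome  position  ref` then one `A:T:C:G:N:del`
#' count string per sample), biallelic encoding: the reference allele is
#' written as A and the rising allele as T. Samples are the line x
#' generation combinations, ordered by line then generation; the column
#' order is returned invisibly and written to `<path>.samples` for
#' round-tripping.
#'
#' @param traj an `er_trajectories` with observed counts
#' @param arch the `er_architecture` supplying coordinates
#' @param path output path
#' @export
write_sync <- function(traj, arch, path) {
  stopifnot(inherits(traj, "er_trajectories"), inherits(arch, "er_architecture"))
  if (anyNA(traj$coverage))
    stop_config("sync output needs observed counts (coverage is NA)")
  key <- paste(traj$line, traj$generation, sep = ".gen")
  samples <- unique(key[order(traj$line, traj$generation)])
  loci <- arch$loci
  counts <- matrix("0:0:0:0:0:0", nrow(loci), length(samples),
                   dimnames = list(loci$locus_id, samples))
  idx <- cbind(match(traj$locus_id, loci$locus_id), match(key, samples))
  counts[idx] <- sprintf("%d:%d:0:0:0:0", traj$coverage - traj$alt_count,
                         traj$alt_count)
  lines_out <- paste(loci$scaffold, loci$position_bp, "A",
                     apply(counts, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines_out, path)
  writeLines(samples, paste0(path, ".samples"))
  invisible(samples)
}

#' Read a popoolation2 sync file as rising-allele counts
#'
#' Biallelic interpretation: per locus, the rising allele is the non-reference
#' base with the highest total count across samples; `alt_count` is its count
#' and `coverage` the total of reference plus rising counts.
#'
#' @param path sync file path
#' @param sample_names optional character vector naming the count columns
#'   (defaults to the `<path>.samples` sidecar if present, else `S1, S2, ...`)
#' @return data.frame with columns scaffold, position_bp, locus_id, sample,
#'   alt_count, coverage, freq
#' @export
read_sync <- function(path, sample_names = NULL) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  n_samp <- ncol(raw) - 3L
  if (n_samp < 1) stop_config("sync file has no sample columns")
  side <- paste0(path, ".samples")
  if (is.null(sample_names) && file.exists(side))
    sample_names <- readLines(side)
  sample_names <- sample_names %||% sprintf("S%d", seq_len(n_samp))
  if (length(sample_names) != n_samp)
    stop_config("sample_names length does not match sync columns")
  bases <- c("A", "T", "C", "G")
  cnt <- array(0L, dim = c(nrow(raw), n_samp, 6L))
  for (j in seq_len(n_samp)) {
    parts <- do.call(rbind, strsplit(raw[[3L + j]], ":", fixed = TRUE))
    cnt[, j, ] <- as.integer(parts)
  }
  ref_idx <- match(toupper(raw[[3]]), bases)
  if (anyNA(ref_idx)) stop_config("reference base must be one of A/T/C/G")
  tot <- apply(cnt[, , 1:4, drop = FALSE], c(1L, 3L), sum)
  tot[cbind(seq_len(nrow(raw)), ref_idx)] <- -1L # exclude ref from argmax
  alt_idx <- max.col(tot, ties.method = "first")
  out <- do.call(rbind, lapply(seq_len(n_samp), function(j) {
    alt <- cnt[cbind(seq_len(nrow(raw)), j, alt_idx)]
    ref <- cnt[cbind(seq_len(nrow(raw)), j, ref_idx)]
    data.frame(scaffold = raw[[1]], position_bp = raw[[2]],
               locus_id = paste(raw[[1]], raw[[2]], sep = "_"),
               sample = sample_names[j],
               alt_count = alt, coverage = alt + ref,
               freq = ifelse(alt + ref > 0, alt / (alt + ref), NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to the defaults of [run_config()].
#' @param path YAML file
#' @return an `er_run_config`
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}
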