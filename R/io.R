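# Plain-text interchange: BED / BEDPE, dense contact-map TSV, loop
# trajectories and conformations. Coordinates are 0-based half-open
# throughout.

#' Read CTCF sites (or other intervals) from a BED file
#'
#' Minimal 6-column BED reader; the strand column carries the CTCF motif
#' orientation (`'+'` = left loop anchor, blocks leftward-moving cohesin
#' legs).
#'
#' @param path BED file (may be gzipped).
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (columns present in the file).
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read dot anchors from a BEDPE file
#'
#' @param path BEDPE file (chrom1 start1 end1 chrom2 start2 end2 ...).
#' @return data.frame with anchor midpoints `pos1`, `pos2` (bp) plus the
#'   raw columns.
#' @export
read_bedpe <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2",
                      "end2")
  df$pos1 <- (df$start1 + df$end1) / 2
  df$pos2 <- (df$start2 + df$end2) / 2
  df
}

#' Write dot anchors as BEDPE
#'
#' @param dots data.frame with `pos1`, `pos2` (bp midpoints).
#' @param path output path.
#' @param chrom chromosome name.
#' @param half_width half-width of the written anchor intervals (bp).
#' @export
write_bedpe <- function(dots, path, chrom = "chrS", half_width = 5000) {
  df <- data.frame(chrom1 = chrom, start1 = pmax(0, dots$pos1 - half_width),
                   end1 = dots$pos1 + half_width, chrom2 = chrom,
                   start2 = pmax(0, dots$pos2 - half_width),
                   end2 = dots$pos2 + half_width)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a contact map as gzipped dense TSV
#'
#' One header line (`# chrom length_bp bin_bp`) followed by the dense
#' matrix.
#'
#' @param map a [contact_map()].
#' @param path output path (`.tsv.gz` recommended).
#' @param chrom chromosome name.
#' @export
write_contact_map <- function(map, path, chrom = "chrS") {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s %d %d", chrom, round(map$length_bp),
                     round(map$bin_bp)), con)
  write.table(map$matrix, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#'
#' @param path input path.
#' @return a [contact_map()].
#' @export
read_contact_map <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  hdr <- strsplit(sub("^#\\s*", "", readLines(con, 1)), "\\s+")[[1]]
  m <- as.matrix(read.table(con, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  contact_map(m, bin_bp = as.numeric(hdr[3]),
              length_bp = as.numeric(hdr[2]))
}

#' Write a loop trajectory as gzipped TSV
#'
#' One row per loop per frame: `time_s`, `species`, `start_bp`, `end_bp`,
#' `status`.
#'
#' @param traj a `loop_trajectory`.
#' @param path output path (`.tsv.gz` recommended).
#' @export
write_trajectory <- function(traj, path) {
  rows <- lapply(traj$frames, function(f) {
    ex <- f$extruders
    if (!nrow(ex)) return(NULL)
    status <- ifelse(ex$stalled_l & ex$stalled_r, "stalled_both",
                     ifelse(ex$stalled_l, "stalled_left",
                            ifelse(ex$stalled_r, "stalled_right",
                                   "extruding")))
    data.frame(time_s = f$time, species = ex$species,
               start_bp = ex$l * f$site_bp, end_bp = ex$r * f$site_bp,
               status = status)
  })
  df <- do.call(rbind, rows)
  con <- gzfile(path, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a loop trajectory table written by [write_trajectory()]
#'
#' @param path input path.
#' @return data.frame (long format, one row per loop per frame).
#' @export
read_trajectory <- function(path) {
  read.table(gzfile(path), sep = "\t", header = TRUE,
             stringsAsFactors = FALSE)
}

#' Write a conformation as CSV
#'
#' Columns: `bead_index`, `chromatid_id`, `genomic_bp`, `x_nm`, `y_nm`,
#' `z_nm`, `flags` (`A` anchor, `L` cohesive link).
#'
#' @param conf a `conformation`.
#' @param path output path.
#' @export
write_conformation <- function(conf, path) {
  b <- conf$beads
  flags <- paste0(ifelse(b$anchor, "A", ""), ifelse(b$link, "L", ""))
  df <- data.frame(bead_index = b$bead, chromatid_id = b$chromatid_id,
                   genomic_bp = b$genomic_bp, x_nm = b$x, y_nm = b$y,
                   z_nm = b$z, flags = flags)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a G2 fixture to YAML (+ BED/BEDPE sidecars)
#'
#' @param fixture a [make_g2_fixture()].
#' @param dir output directory (created if needed).
#' @param name basename for the files.
#' @return the YAML path, invisibly. Requires the `yaml` package.
#' @export
write_g2_fixture <- function(fixture, dir, name = "g2_fixture") {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to write fixtures")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, paste0(name, "_ctcf.bed"))
  write_bed(data.frame(chrom = "chrS",
                       start = fixture$ctcf$pos * fixture$site_bp,
                       end = (fixture$ctcf$pos + 1) * fixture$site_bp,
                       name = "CTCF", score = 0,
                       strand = fixture$ctcf$strand), bed)
  bedpe <- file.path(dir, paste0(name, "_dots.bedpe"))
  if (NROW(fixture$expected_dots)) {
    write_bedpe(fixture$expected_dots, bedpe)
  }
  meta <- list(length_bp = fixture$length_bp, site_bp = fixture$site_bp,
               cohesin = fixture$cohesin[c("name", "density", "speed",
                                           "loading_rate",
                                           "unloading_rate")],
               label_bin_bp = fixture$label_bin_bp,
               ab_labels = paste(fixture$ab_labels, collapse = ""),
               seed = fixture$seed, ctcf_bed = basename(bed),
               dots_bedpe = basename(bedpe))
  path <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(meta, path)
  invisible(path)
}
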