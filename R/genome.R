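#' Generate a synthetic genome with planted features
#'
#' Builds a random genome emulating an annotated reference assembly: i.i.d.
#' bases at a configurable GC fraction, plus optional planted motifs, polyA
#' runs, repeat intervals and labelled element intervals at caller-chosen or
#' randomly drawn coordinates. All coordinates are 0-based half-open
#' (BED convention). Generation is fully deterministic per seed.
#'
#' Planted features must not overlap one another; collisions are rejected
#' with a message naming the colliding intervals. PolyA runs are planted with
#' a \code{C} immediately before and after the run so that leading-T trimming
#' of reads primed at the run is unambiguous.
#'
#' @param chrom_lengths named integer vector, chromosome name -> length.
#' @param gc numeric in (0,1), target GC fraction (default 0.41, typical of
#'   the human genome).
#' @param motifs optional data.frame with columns \code{chrom,start,strand,
#'   motif} (motif written verbatim on '+', reverse-complemented on '-'), or
#'   a list \code{list(motif=, n=, chrom=)} asking for \code{n} random
#'   non-overlapping placements.
#' @param polyA_runs optional data.frame \code{chrom,start,length} or list
#'   \code{list(n=, length=, chrom=)} for random placement (default length
#'   12).
#' @param repeats optional data.frame \code{chrom,start,end} of intervals to
#'   annotate (and fill with an AT-biased "repeat-like" sequence), or list
#'   \code{list(n=, length=, chrom=)}.
#' @param elements optional named list of data.frames \code{chrom,start,end}
#'   annotating element classes (promoter, exon, ...). Element annotations
#'   are labels only; they do not alter the sequence and may overlap planted
#'   features.
#' @param seed integer seed.
#' @return an object of class \code{ssb_genome}: list with \code{sequences}
#'   (named character), \code{motifs}, \code{polyA_runs}, \code{repeats}
#'   (data.frames, 0-based half-open), \code{elements} (named list),
#'   \code{seed}.
#' @examples
#' g <- make_genome(c(chrA = 10000), seed = 1)
#' nchar(g$sequences[["chrA"]])
#' @export
make_genome <- function(chrom_lengths, gc = 0.41, motifs = NULL,
                        polyA_runs = NULL, repeats = NULL, elements = NULL,
                        seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector", call. = FALSE)
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)

  set.seed(as.integer(seed))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sequences <- lapply(chrom_lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = p), collapse = "")
  })

  planted <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), what = character(0))
  reserve <- function(chrom, start, end, what) {
    hit <- planted[planted$chrom == chrom &
                     planted$start < end & start < planted$end, , drop = FALSE]
    if (nrow(hit) > 0) {
      stop(sprintf(
        "planted feature %s %s:[%d,%d) collides with %s %s:[%d,%d)",
        what, chrom, start, end,
        hit$what[1], hit$chrom[1], hit$start[1], hit$end[1]), call. = FALSE)
    }
    planted[nrow(planted) + 1L, ] <<- list(chrom, as.integer(start),
                                           as.integer(end), what)
  }
  random_starts <- function(n, width, chrom) {
    L <- chrom_lengths[[chrom]]
    out <- integer(0)
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 200L * n)
        stop("could not place planted features without overlap", call. = FALSE)
      s <- sample.int(L - width - 1L, 1L)  # 1-based draw, avoid edges
      ok <- !any(planted$chrom == chrom & planted$start < s + width &
                   s < planted$end)
      ok <- ok && !any(out < s + width & s < out + width)
      if (ok) out <- c(out, s)
    }
    sort(out)
  }
  write_seq <- function(chrom, start, str) {
    substr(sequences[[chrom]], start + 1L, start + nchar(str)) <<- str
  }

  ## motifs
  motif_df <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         motif = character(0), stringsAsFactors = FALSE)
  if (!is.null(motifs)) {
    if (is.data.frame(motifs)) {
      mdf <- motifs
      if (is.null(mdf$strand)) mdf$strand <- "+"
    } else {
      chrom <- motifs$chrom %||% names(chrom_lengths)[1]
      w <- nchar(motifs$motif)
      st <- random_starts(motifs$n, w, chrom)
      mdf <- data.frame(chrom = chrom, start = st,
                        strand = rep_len(motifs$strand %||% "+", motifs$n),
                        motif = motifs$motif, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(mdf))) {
      w <- nchar(mdf$motif[i])
      reserve(mdf$chrom[i], mdf$start[i], mdf$start[i] + w, "motif")
      s <- if (mdf$strand[i] == "+") mdf$motif[i] else revcomp(mdf$motif[i])
      write_seq(mdf$chrom[i], mdf$start[i], s)
    }
    motif_df <- data.frame(chrom = mdf$chrom, start = as.integer(mdf$start),
                           end = as.integer(mdf$start + nchar(mdf$motif)),
                           strand = mdf$strand, motif = mdf$motif,
                           stringsAsFactors = FALSE)
  }

  ## polyA runs (flanked by C on both sides so T-run trimming is clean)
  polyA_df <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  if (!is.null(polyA_runs)) {
    if (is.data.frame(polyA_runs)) {
      adf <- polyA_runs
      if (is.null(adf$length)) adf$length <- adf$end - adf$start
    } else {
      chrom <- polyA_runs$chrom %||% names(chrom_lengths)[1]
      len <- polyA_runs$length %||% 12L
      st <- random_starts(polyA_runs$n, len + 2L, chrom) + 1L
      adf <- data.frame(chrom = chrom, start = st, length = len,
                        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(adf))) {
      s <- adf$start[i]; r <- adf$length[i]
      reserve(adf$chrom[i], s - 1L, s + r + 1L, "polyA")
      write_seq(adf$chrom[i], s - 1L,
                paste0("C", strrep("A", r), "C"))
    }
    polyA_df <- data.frame(chrom = adf$chrom, start = as.integer(adf$start),
                           end = as.integer(adf$start + adf$length),
                           stringsAsFactors = FALSE)
  }

  ## repeat intervals: annotated and filled with an AT-rich low-complexity fill
  repeat_df <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
  if (!is.null(repeats)) {
    if (is.data.frame(repeats)) {
      rdf <- repeats
    } else {
      chrom <- repeats$chrom %||% names(chrom_lengths)[1]
      len <- repeats$length %||% 300L
      st <- random_starts(repeats$n, len, chrom)
      rdf <- data.frame(chrom = chrom, start = st, end = st + len,
                        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(rdf))) {
      reserve(rdf$chrom[i], rdf$start[i], rdf$end[i], "repeat")
      w <- rdf$end[i] - rdf$start[i]
      fill <- paste(sample(DNA_BASES, w, replace = TRUE,
                           prob = c(.35, .15, .15, .35)), collapse = "")
      write_seq(rdf$chrom[i], rdf$start[i], fill)
    }
    repeat_df <- data.frame(chrom = rdf$chrom, start = as.integer(rdf$start),
                            end = as.integer(rdf$end), stringsAsFactors = FALSE)
  }

  bounds_ok <- function(df) {
    all(df$start >= 0 & df$end <= chrom_lengths[df$chrom])
  }
  for (df in list(motif_df, polyA_df, repeat_df))
    if (nrow(df) > 0 && !bounds_ok(df))
      stop("planted feature outside chromosome bounds", call. = FALSE)
  if (!is.null(elements)) {
    for (nm in names(elements))
      if (nrow(elements[[nm]]) > 0 && !bounds_ok(elements[[nm]]))
        stop(sprintf("element '%s' outside chromosome bounds", nm), call. = FALSE)
  }

  structure(list(sequences = sequences, motifs = motif_df,
                 polyA_runs = polyA_df, repeats = repeat_df,
                 elements = elements %||% list(), seed = as.integer(seed)),
            class = "ssb_genome")
}

#' @export
print.ssb_genome <- function(x, ...) {
  cat("Synthetic genome:", length(x$sequences), "chromosome(s),",
      sum(nchar(unlist(x$sequences))), "bp total\n")
  cat("  motifs:", nrow(x$motifs), " polyA runs:", nrow(x$polyA_runs),
      " repeat intervals:", nrow(x$repeats),
      " element classes:", length(x$elements), "\n")
  invisible(x)
}

#' Chromosome lengths of a synthetic genome
#' @param genome an \code{ssb_genome}.
#' @return named integer vector.
#' @export
genome_lengths <- function(genome) {
  vapply(genome$sequences, nchar, integer(1))
}

#' Write a genome to FASTA
#' @param genome an \code{ssb_genome}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome$sequences))
  names(ss) <- names(genome$sequences)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read a FASTA genome
#' @param path FASTA file.
#' @return an \code{ssb_genome} with empty annotations.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  structure(list(sequences = as.list(as.character(ss)),
                 motifs = data.frame(), polyA_runs = data.frame(),
                 repeats = data.frame(), elements = list(), seed = NA_integer_),
            class = "ssb_genome")
}

#' Count and locate motif sites in a genome
#'
#' Scans every chromosome for exact occurrences of a motif on both strands
#' (a palindromic motif is reported once, on '+'). Used e.g. to enumerate
#' restriction/nickase recognition sites such as AsiSI (GCGATCGC) or
#' Nt.BbvCI (CCTCAGC).
#'
#' @param genome an \code{ssb_genome}.
#' @param motif character scalar, IUPAC not supported (exact match).
#' @return data.frame \code{chrom,start,end,strand} (0-based half-open).
#' @export
find_motif_sites <- function(genome, motif) {
  pal <- identical(motif, revcomp(motif))
  hits_df <- function(chrom, m, strand) {
    data.frame(chrom = rep(chrom, length(m)),
               start = Biostrings::start(m) - 1L,
               end = Biostrings::end(m), strand = rep(strand, length(m)),
               stringsAsFactors = FALSE)
  }
  out <- lapply(names(genome$sequences), function(chrom) {
    subj <- Biostrings::DNAString(genome$sequences[[chrom]])
    res <- hits_df(chrom, Biostrings::matchPattern(motif, subj), "+")
    if (!pal) {
      res <- rbind(res, hits_df(chrom,
                                Biostrings::matchPattern(revcomp(motif), subj),
                                "-"))
    }
    res
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' @rdname find_motif_sites
#' @return \code{count_motif_sites}: integer site count.
#' @export
count_motif_sites <- function(genome, motif) {
  nrow(find_motif_sites(genome, motif))
}
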