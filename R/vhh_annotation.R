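# Framework/CDR annotation of VHH (nanobody) domains and humanization
# bookkeeping. Positions are sequential 1-based over the domain; the 121-
# residue scheme below is the classic layout of a VHH single domain. Kabat
# equivalents are carried as metadata only for the camelid hallmark
# positions, where the mapping is established.

.vhh_region_names <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

# experimentally preferred humanization positions ("hotspots")
.vhh_hotspots <- c(14L, 41L, 44L, 76L, 85L, 116L)

# camelid hallmark positions distinguishing VHH from human VH, with their
# Kabat-numbering equivalents
.vhh_hallmarks <- data.frame(
  position = c(11L, 34L, 41L, 42L, 44L),
  kabat    = c(11L, 37L, 44L, 45L, 47L)
)

#' Build and validate a FR/CDR region map
#'
#' @param name,start,end parallel vectors describing the ordered segments.
#'   Segments must be contiguous, non-overlapping, cover 1..L exactly, and
#'   appear in the canonical order FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4.
#' @return a `region_map` data.frame with columns `name`, `start`, `end`.
#' @export
region_map <- function(name, start, end) {
  rm_ <- data.frame(name = as.character(name), start = as.integer(start),
                    end = as.integer(end))
  if (!identical(rm_$name, .vhh_region_names)) {
    stop("regions must be exactly FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4 in order")
  }
  if (rm_$start[1] != 1L) stop("first segment must start at 1")
  if (any(rm_$end < rm_$start)) stop("segment with end < start")
  gaps <- rm_$start[-1] != rm_$end[-nrow(rm_)] + 1L
  if (any(gaps)) {
    stop("segments must tile the sequence; gap/overlap before ",
         rm_$name[-1][gaps][1])
  }
  class(rm_) <- c("region_map", "data.frame")
  rm_
}

#' The built-in 121-residue VHH region scheme
#'
#' FR1 1-25, CDR1 26-30, FR2 31-48, CDR2 49-56, FR3 57-93, CDR3 94-109,
#' FR4 110-121.
#'
#' @param L domain length; the built-in scheme is defined for L = 121 only,
#'   any other length requires a user-supplied [region_map()].
#' @return a `region_map`.
#' @export
default_region_map <- function(L = 121L) {
  if (L != 121L) {
    stop("built-in scheme is for L = 121; supply a region_map() for other lengths")
  }
  region_map(.vhh_region_names,
             start = c(1L, 26L, 31L, 49L, 57L, 94L, 110L),
             end   = c(25L, 30L, 48L, 56L, 93L, 109L, 121L))
}

#' Region containing each position
#'
#' @param positions integer vector of 1-based positions.
#' @param regions a `region_map`.
#' @return character vector of region names.
#' @export
region_of <- function(positions, regions) {
  idx <- findInterval(positions, regions$start)
  if (any(positions < 1 | positions > regions$end[nrow(regions)])) {
    stop("position outside region map")
  }
  regions$name[idx]
}

#' Point-mutation diff of two equal-length sequences
#'
#' The humanization scheme introduces substitutions only (no indels), so the
#' two sequences must have equal length.
#'
#' @param wild,variant character vectors of one-letter codes (or single
#'   strings).
#' @return data.frame of class `mutation_list` with columns `original`,
#'   `position`, `replacement`, `notation` ("X{pos}Y"), ascending by
#'   position; zero rows when the sequences are identical.
#' @export
diff_sequences <- function(wild, variant) {
  wild <- .as_residues(wild); variant <- .as_residues(variant)
  if (length(wild) != length(variant)) {
    stop("sequences differ in length; indels are not supported")
  }
  pos <- which(wild != variant)
  mutation_list(wild[pos], pos, variant[pos])
}

.as_residues <- function(x) {
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  toupper(x)
}

#' Construct a mutation list
#'
#' @param original,replacement one-letter codes; `position` 1-based ints.
#' @param position integer positions.
#' @return `mutation_list` data.frame.
#' @export
mutation_list <- function(original, position, replacement) {
  stopifnot(length(original) == length(position),
            length(replacement) == length(position))
  if (any(original == replacement)) stop("original equals replacement")
  o <- order(position)
  structure(data.frame(original = original[o],
                       position = as.integer(position[o]),
                       replacement = replacement[o],
                       notation = paste0(original[o], position[o],
                                         replacement[o])),
            class = c("mutation_list", "data.frame"))
}

#' Parse "X{pos}Y" notations into a mutation list
#' @param notation character vector like `c("Q5V", "S11L")`.
#' @export
parse_mutations <- function(notation) {
  m <- regmatches(notation, regexec("^([A-Z])([0-9]+)([A-Z])$", notation))
  if (any(lengths(m) != 4)) stop("bad mutation notation")
  mutation_list(vapply(m, `[`, "", 2), as.integer(vapply(m, `[`, "", 3)),
                vapply(m, `[`, "", 4))
}

#' Apply a mutation list to a sequence
#'
#' @param sequence one-letter vector or string.
#' @param mutations a `mutation_list`.
#' @return mutated sequence as a character vector; errors if the sequence
#'   does not carry the expected original residues.
#' @export
apply_mutations <- function(sequence, mutations) {
  s <- .as_residues(sequence)
  if (any(mutations$position > length(s))) stop("mutation beyond sequence end")
  bad <- s[mutations$position] != mutations$original
  if (any(bad)) {
    stop("sequence does not match mutation original(s): ",
         paste(mutations$notation[bad], collapse = ", "))
  }
  s[mutations$position] <- mutations$replacement
  s
}

#' Percentage of mutated residues
#'
#' @param mutations a `mutation_list` (or its row count).
#' @param L domain length.
#' @return `100 * n_mutations / L`, rounded to 1 decimal.
#' @export
percent_mutated <- function(mutations, L) {
  stopifnot(L > 0)
  n <- if (is.data.frame(mutations)) nrow(mutations) else as.integer(mutations)
  round(100 * n / L, 1)
}

#' Annotate mutations with region, hotspot and hallmark status
#'
#' Flags depend only on the sequential position: humanization hotspots are
#' positions 14, 41, 44, 76, 85 and 116; camelid hallmark positions (VHH vs
#' VH) are 11, 34, 41, 42 and 44, carried with their Kabat equivalents.
#'
#' @param mutations a `mutation_list`.
#' @param regions a `region_map`.
#' @return data.frame with columns `notation`, `position`, `region`,
#'   `hotspot`, `hallmark`, `kabat` (Kabat notation for hallmark positions,
#'   `NA` otherwise).
#' @export
classify_mutations <- function(mutations, regions) {
  reg <- region_of(mutations$position, regions)
  hm <- match(mutations$position, .vhh_hallmarks$position)
  kabat <- ifelse(is.na(hm), NA_character_,
                  paste0(mutations$original, .vhh_hallmarks$kabat[hm],
                         mutations$replacement))
  data.frame(notation = mutations$notation,
             position = mutations$position,
             region = reg,
             hotspot = mutations$position %in% .vhh_hotspots,
             hallmark = !is.na(hm),
             kabat = kabat)
}

#' The humanization mutation sets of the HL6 case study
#'
#' The structure-guided scenario carries 12 substitutions; the sequence-only
#' scenario carries those 12 plus F34V, R42L and K84R (15 in total).
#'
#' @param scenario `"structure"` (12 mutations) or `"sequence"` (15).
#' @return a `mutation_list`.
#' @export
hl6_humanization_mutations <- function(scenario = c("structure", "sequence")) {
  scenario <- match.arg(scenario)
  core <- c("Q5V", "S11L", "A14P", "S23A", "E41G", "G44W",
            "Q69R", "V76L", "P85A", "M90V", "A95R", "E116L")
  extra <- c("F34V", "R42L", "K84R")
  parse_mutations(if (scenario == "structure") core else c(core, extra))
}

#' Write a mutation audit as TSV
#'
#' Columns: notation, position, region, hotspot, hallmark, kabat.
#'
#' @param annotated output of [classify_mutations()].
#' @param path output file.
#' @export
write_mutation_table <- function(annotated, path) {
  utils::write.table(annotated, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
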