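# Cross-species comparison of methylation at homologous structural
# positions, with the three-class conservation scheme:
#   class1 - methylated in every classifiable species;
#   class2 - methylated in all but one species, which carries a SNP
#            (a non-C base) at the position;
#   class3 - methylated in at least one species while at least one other
#            species has a cytosine there but is unmethylated.
# Species without confident coverage (no_call) are excluded from the class
# decision rather than counted as unmethylated; a site classifiable in
# fewer than 3 species is "unclassified".

#' Build a cross-species conservation table for structural sites
#'
#' @param species_calls named list (one element per species) of
#'   [call_sites()] outputs restricted to one RNA family, with an added
#'   `structural_position` column (from [assign_trna_structure()] or
#'   [lift_rrna_position()]).
#' @param species_refs named list (same names) of the species' reference
#'   sequences for the RNA, as single strings.
#' @param species_maps named list (same names) of objects mapping sequence
#'   index to structural position: either a `structural_map` or a
#'   `coordinate_lift`.
#' @param ambiguous_positions optional data.frame (`species`,
#'   `structural_position`) of positions whose base cannot be resolved
#'   (e.g. C-or-T); these exclude the species from classification at that
#'   position.
#' @return data.frame of class `conservation_table`, long format: one row
#'   per (structural position methylated in >= 1 species) x species, columns
#'   `structural_position`, `species`, `base_state` (`C`, `SNP:<base>`,
#'   `absent`, `ambiguous`), `methylation`, `status`, `color_bin`, `class`.
#' @export
build_conservation_table <- function(species_calls, species_refs,
                                     species_maps,
                                     ambiguous_positions = NULL) {
  sp <- names(species_calls)
  if (length(sp) < 2L)
    stop("need calls from at least 2 species", call. = FALSE)
  if (!setequal(sp, names(species_refs)) || !setequal(sp, names(species_maps)))
    stop("species_calls, species_refs and species_maps must cover the same species",
         call. = FALSE)
  for (s in sp)
    if (is.null(species_maps[[s]]))
      stop("species without a structural map: ", s, call. = FALSE)

  # structural positions methylated in >= 1 species
  meth_pos <- sort(unique(unlist(lapply(species_calls, function(x)
    x$structural_position[x$status == "methylated"]))))
  if (length(meth_pos) == 0L)
    return(structure(empty_conservation_table(), class =
                       c("conservation_table", "data.frame")))

  seq_index_at <- function(map, spos) {
    m <- if (inherits(map, "structural_map")) map$mapping else map$map
    idx_col <- if (inherits(map, "structural_map")) "seq_index" else "species_pos"
    lab_col <- if (inherits(map, "structural_map")) "structural_position" else "anchor_pos"
    m[[idx_col]][match(spos, m[[lab_col]])]
  }

  rows <- list()
  for (p in meth_pos) {
    cells <- lapply(sp, function(s) {
      calls <- species_calls[[s]]
      ref_chars <- seq_chars(species_refs[[s]])
      idx <- seq_index_at(species_maps[[s]], p)
      amb <- !is.null(ambiguous_positions) &&
        any(ambiguous_positions$species == s &
              ambiguous_positions$structural_position == p)
      base_state <- if (amb) "ambiguous"
        else if (is.na(idx)) "absent"
        else if (ref_chars[idx] == "C") "C"
        else paste0("SNP:", ref_chars[idx])
      hit <- which(calls$structural_position == p)
      status <- if (length(hit)) calls$status[hit[1]] else "no_call"
      methylation <- if (length(hit) && base_state == "C" &&
                         status != "no_call") calls$methylation[hit[1]]
        else NA_real_
      list(species = s, base_state = base_state, status = status,
           methylation = methylation)
    })
    cls <- classify_site(cells)
    for (cell in cells) {
      rows[[length(rows) + 1L]] <- data.frame(
        structural_position = p,
        species = cell$species,
        base_state = cell$base_state,
        methylation = cell$methylation,
        status = if (cell$base_state == "C") cell$status else NA_character_,
        color_bin = if (!is.na(cell$methylation))
          color_bin(cell$methylation)$bin else NA_character_,
        class = cls,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("conservation_table", "data.frame"))
}

empty_conservation_table <- function() {
  data.frame(structural_position = integer(), species = character(),
             base_state = character(), methylation = numeric(),
             status = character(), color_bin = character(),
             class = character(), stringsAsFactors = FALSE)
}

# classification of one structural position from its per-species cells
classify_site <- function(cells) {
  base_state <- vapply(cells, `[[`, character(1), "base_state")
  status <- vapply(cells, `[[`, character(1), "status")
  # classifiable: base resolved and, where a C is present, confidently
  # covered; ambiguous bases and no_call coverage drop the species
  has_c <- base_state == "C"
  classifiable <- (has_c & status != "no_call") | startsWith(base_state, "SNP")
  n_cls <- sum(classifiable)
  if (n_cls < 3L) return("unclassified")
  methylated <- classifiable & has_c & status == "methylated"
  unmeth_c <- classifiable & has_c & status == "unmethylated"
  snp <- classifiable & startsWith(base_state, "SNP")
  if (!any(methylated)) return("unclassified")
  if (all(methylated[classifiable])) return("class1")
  if (sum(snp) == 1L && all(methylated[classifiable & !snp])) return("class2")
  if (any(unmeth_c)) return("class3")
  "unclassified"
}

#' Colour bin for a methylation fraction
#'
#' Bins follow the percent-methylation colour scheme used for circular
#' conservation plots: 0-40 % low (green end), 80-100 % high (red end),
#' in-between an interpolated gradient value.
#'
#' @param methylation fraction in \[0,1\].
#' @return list with `bin` (`"low"`, `"intermediate"`, `"high"`) and
#'   `gradient` (0 at 40 % rising to 1 at 80 %; 0 for low, 1 for high).
#' @export
color_bin <- function(methylation) {
  if (is.na(methylation) || methylation < 0 || methylation > 1)
    stop("methylation must lie in [0,1]", call. = FALSE)
  if (methylation <= 0.40) list(bin = "low", gradient = 0)
  else if (methylation >= 0.80) list(bin = "high", gradient = 1)
  else list(bin = "intermediate",
            gradient = (methylation - 0.40) / 0.40)
}

#' Summary of conservation class counts
#'
#' @param tab a [build_conservation_table()] result.
#' @return named integer vector of site counts per class.
#' @export
conservation_class_counts <- function(tab) {
  per_site <- unique(tab[, c("structural_position", "class")])
  counts <- table(factor(per_site$class,
                         levels = c("class1", "class2", "class3",
                                    "unclassified")))
  setNames(as.integer(counts), names(counts))
}
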