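#' Conserved TFs between two species' intersection zones
#'
#' TFs present in both species' selected lists. By default human and mouse
#' TF symbols are matched case-insensitively (SP1 and Sp1 are the same
#' factor); an explicit `tf_name_map` (human id -> mouse id) overrides
#' this. Output keeps the human rank order.
#'
#' @param human_zone,mouse_zone `intersection_zone` objects computed with
#'   the same pipeline settings.
#' @param tf_name_map optional named character vector mapping human TF ids
#'   to mouse TF ids; must be injective.
#' @return character vector of human TF ids conserved in mouse.
#' @export
conserved_tfs <- function(human_zone, mouse_zone, tf_name_map = NULL) {
  h <- human_zone$tfs
  if (!is.null(tf_name_map) && anyDuplicated(tf_name_map[!is.na(tf_name_map)])) {
    stop("tf_name_map maps two human TFs to the same mouse TF")
  }
  mapped <- if (is.null(tf_name_map)) {
    h
  } else {
    ifelse(h %in% names(tf_name_map), unname(tf_name_map[h]), h)
  }
  h[tolower(mapped) %in% tolower(mouse_zone$tfs)]
}

#' Classify a TF's pathway scope from its zone hits
#'
#' A factor hitting genes of exactly one pathway module is
#' "process-specific"; one hitting several modules is
#' "pathway-ubiquitous". A factor with no zone hits is unclassifiable
#' (scope `NA`).
#'
#' @param tf_id the TF.
#' @param zone an `intersection_zone`.
#' @param module_annotation named character vector gene id -> module label;
#'   zone genes absent from it are `"unassigned"`.
#' @return list with `tf_id`, `scope` (`"process-specific"`,
#'   `"pathway-ubiquitous"` or `NA`), and `modules_hit`.
#' @export
classify_scope <- function(tf_id, zone, module_annotation) {
  if (!tf_id %in% zone$tfs) stop("TF ", tf_id, " is not in the zone")
  hit_genes <- zone$genes[zone$submatrix[, tf_id] > 0]
  mods <- module_annotation[hit_genes]
  mods[is.na(mods)] <- "unassigned"
  mods <- sort(unique(unname(mods)))
  scope <- if (length(mods) == 0) {
    NA_character_
  } else if (length(mods) == 1) {
    "process-specific"
  } else {
    "pathway-ubiquitous"
  }
  list(tf_id = tf_id, scope = scope, modules_hit = mods)
}

#' Flag a high-affinity TF
#'
#' A factor with more than three accepted occurrences in a single gene's
#' promoter (strictly exceeding three) — multiple tandem copies being read
#' as a strong-binding, high-affinity configuration.
#'
#' @param tf_id the TF.
#' @param counts gene x TF count matrix.
#' @return logical scalar.
#' @export
flag_high_affinity <- function(tf_id, counts) {
  if (!tf_id %in% colnames(counts)) stop("TF ", tf_id, " is not in the matrix")
  max(counts[, tf_id]) > 3
}

#' Look up a TF's regulatory direction from an annotation table
#'
#' Direction (regulating the pathway vs regulated by it) comes from
#' curated literature annotation, never from the motif data; factors absent
#' from the table are `"unannotated"`.
#'
#' @param tf_id the TF.
#' @param direction_config data.frame (tf_id, direction), a named character
#'   vector, or a path to a YAML file mapping TF id -> direction. Allowed
#'   directions: regulating, regulated, both.
#' @return one of `"regulating"`, `"regulated"`, `"both"`, `"unannotated"`.
#' @export
annotate_direction <- function(tf_id, direction_config) {
  tab <- direction_table(direction_config)
  if (!tf_id %in% names(tab)) return("unannotated")
  unname(tab[tf_id])
}

## normalize the accepted config forms to a validated named vector
direction_table <- function(direction_config) {
  if (is.character(direction_config) && length(direction_config) == 1 &&
      file.exists(direction_config)) {
    direction_config <- unlist(yaml::read_yaml(direction_config))
  }
  if (is.data.frame(direction_config)) {
    if (!all(c("tf_id", "direction") %in% names(direction_config))) {
      stop("direction config data.frame needs columns tf_id, direction")
    }
    dup <- duplicated(direction_config$tf_id)
    if (any(dup)) {
      conf <- direction_config[direction_config$tf_id %in%
                                 direction_config$tf_id[dup], ]
      if (nrow(unique(conf)) != length(unique(conf$tf_id))) {
        stop("conflicting duplicate direction rows for: ",
             paste(unique(conf$tf_id), collapse = ", "))
      }
      direction_config <- direction_config[!dup, ]
    }
    tab <- stats::setNames(direction_config$direction, direction_config$tf_id)
  } else if (!is.null(names(direction_config))) {
    tab <- direction_config
  } else {
    stop("malformed direction config")
  }
  bad <- setdiff(unique(tab), c("regulating", "regulated", "both"))
  if (length(bad)) {
    stop("invalid direction values: ", paste(bad, collapse = ", "))
  }
  tab
}

#' Full classification report for the zone TFs
#'
#' One row per selected TF: pathway scope, modules hit, high-affinity flag,
#' cross-species conservation, and literature direction.
#'
#' @param zone the species' `intersection_zone`.
#' @param counts the full count matrix the zone came from (high-affinity is
#'   judged over the whole dataset).
#' @param module_annotation named vector gene id -> module label.
#' @param direction_config see [annotate_direction()]; `NULL` leaves all
#'   factors unannotated.
#' @param conserved character vector of conserved TF ids (e.g. from
#'   [conserved_tfs()]).
#' @return data.frame (tf_id, scope, modules_hit, n_modules, high_affinity,
#'   conserved, direction).
#' @export
classify_tfs <- function(zone, counts, module_annotation,
                         direction_config = NULL, conserved = character()) {
  rows <- lapply(zone$tfs, function(tf) {
    sc <- classify_scope(tf, zone, module_annotation)
    data.frame(
      tf_id = tf,
      scope = if (is.na(sc$scope)) "unclassifiable" else sc$scope,
      modules_hit = paste(sc$modules_hit, collapse = ","),
      n_modules = length(sc$modules_hit),
      high_affinity = flag_high_affinity(tf, counts),
      conserved = tf %in% conserved,
      direction = if (is.null(direction_config)) "unannotated"
                  else annotate_direction(tf, direction_config),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
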