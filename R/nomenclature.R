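#' @title Gene-name synonym resolution
#'
#' @description Across published brain proteomics studies the same protein is
#' reported under different gene symbols (e.g. a RIKEN clone identifier in one
#' study and the official symbol in eleven others), and some studies report
#' only UniProt accessions. These functions unify such labels by building a
#' graph in which gene names are vertices and names co-listed on one data
#' entry (or one synonym-table row) are connected by an edge; every connected
#' component is a set of potential synonyms, and each component is assigned a
#' single canonical symbol -- the name used most often across data entries.
#'
#' @name nomenclature
NULL

# Uppercase, whitespace-trimmed name; comparison is case-insensitive so
# mouse-style symbols (Stxbp1) and human-style symbols (STXBP1) unify.
norm_gene_name <- function(x) toupper(trimws(x))

#' Build a gene-name synonym graph from co-listed names
#'
#' Vertices are gene names; an edge joins two names listed together on the
#' same data entry or on the same synonym-table row. Connected components are
#' treated as synonym sets. Each component's canonical name is the member
#' occurring in the largest number of data entries; ties are broken in favour
#' of names present in the (mouse-derived) synonym table, then by
#' lexicographic order, so the result is deterministic.
#'
#' @param entries list of character vectors; each vector holds the gene names
#'   co-listed on one data entry. Names are compared case-insensitively.
#' @param synonym_table optional list of character vectors of synonymous names
#'   (e.g. the `gene_names` column of [read_synonym_table()] output, split on
#'   `|`). These contribute edges and mark table membership for tie-breaking,
#'   but do not contribute to occurrence counts.
#' @return An object of class `synonym_graph` with elements `graph` (igraph),
#'   `membership` (named integer vector: vertex -> component id),
#'   `components` (list of character vectors), `canonical_map` (named
#'   character vector: vertex -> canonical name), `counts` (entry occurrence
#'   count per vertex) and `in_table` (logical per vertex).
#' @examples
#' g <- build_synonym_graph(list(c("A", "B"), c("B", "C"), "D"))
#' g$canonical_map[["A"]] # "B": most frequent member of {A,B,C}
#' @export
build_synonym_graph <- function(entries, synonym_table = list()) {
  if (length(entries) == 0L) stop("no entries")
  check_lists <- function(lists, what) {
    for (i in seq_along(lists)) {
      nm <- norm_gene_name(lists[[i]])
      if (length(nm) == 0L) stop(sprintf("%s %d is empty", what, i))
      if (any(!nzchar(nm)) || any(is.na(nm)))
        stop(sprintf("blank name in %s %d", what, i))
      lists[[i]] <- nm
    }
    lists
  }
  entries <- check_lists(entries, "entry")
  synonym_table <- if (length(synonym_table)) {
    check_lists(synonym_table, "synonym-table row")
  } else {
    list()
  }

  all_lists <- c(entries, synonym_table)
  vertices <- sort(unique(unlist(all_lists, use.names = FALSE)))

  # Chain edges within a list are enough to make its names one component.
  edge_pairs <- lapply(all_lists, function(nm) {
    nm <- unique(nm)
    if (length(nm) < 2L) return(NULL)
    cbind(nm[-length(nm)], nm[-1L])
  })
  edges <- do.call(rbind, edge_pairs)

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(vertices), name = vertices)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(matrix(match(edges, vertices), ncol = 2L)))
  }
  comp <- igraph::components(g)
  membership <- comp$membership
  names(membership) <- vertices

  # Occurrence count: number of data entries (not table rows) listing a name.
  counts <- stats::setNames(integer(length(vertices)), vertices)
  for (nm in entries) {
    nm <- unique(nm)
    counts[nm] <- counts[nm] + 1L
  }
  in_table <- stats::setNames(
    vertices %in% unlist(synonym_table, use.names = FALSE), vertices)

  canonical_map <- stats::setNames(character(length(vertices)), vertices)
  for (members in split(vertices, membership[vertices])) {
    ord <- order(-counts[members], !in_table[members], members)
    canonical_map[members] <- members[ord[1L]]
  }

  structure(
    list(graph = g, membership = membership,
         components = unname(split(vertices, membership[vertices])),
         canonical_map = canonical_map, counts = counts, in_table = in_table),
    class = "synonym_graph")
}

#' @export
print.synonym_graph <- function(x, ...) {
  cat(sprintf("synonym_graph: %d names in %d components\n",
              length(x$canonical_map), length(x$components)))
  invisible(x)
}

#' Create an identifier record
#'
#' One raw protein identification as reported by a source study: any number
#' of gene names and/or UniProt accessions, at least one of which must be
#' present.
#'
#' @param raw_gene_names character vector of reported gene names (may be empty)
#' @param raw_accessions character vector of UniProt accessions (may be empty)
#' @return a list of class `identifier_record` with unset canonical fields
#' @export
identifier_record <- function(raw_gene_names = character(),
                              raw_accessions = character()) {
  raw_gene_names <- raw_gene_names[nzchar(trimws(raw_gene_names))]
  raw_accessions <- raw_accessions[nzchar(trimws(raw_accessions))]
  if (length(raw_gene_names) == 0L && length(raw_accessions) == 0L)
    stop("record needs at least one gene name or accession")
  structure(
    list(raw_gene_names = as.character(raw_gene_names),
         raw_accessions = trimws(as.character(raw_accessions)),
         canonical_gene = NA_character_,
         canonical_accession = NA_character_,
         conflict_flag = FALSE),
    class = "identifier_record")
}

#' Read an offline UniProt-derived synonym table
#'
#' Tab-separated file with columns `accession`, `gene_names` (pipe-separated
#' synonyms) and `species`. This file replaces live UniProt queries so that
#' runs are reproducible offline.
#'
#' @param path file path
#' @return data.frame with columns `accession`, `gene_names` (list column of
#'   uppercase character vectors), `species`
#' @export
read_synonym_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("accession", "gene_names", "species")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("synonym table missing column ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(trimws(tab$accession[i])) || !nzchar(trimws(tab$gene_names[i])))
      stop(sprintf("malformed synonym table row %d", i))
  }
  tab$gene_names <- lapply(strsplit(tab$gene_names, "|", fixed = TRUE),
                           norm_gene_name)
  tab$accession <- trimws(tab$accession)
  tab
}

# accession -> first gene name, and name -> accessions, from a parsed table
synonym_table_maps <- function(synonym_table) {
  acc2gene <- stats::setNames(
    vapply(synonym_table$gene_names, `[`, character(1), 1L),
    synonym_table$accession)
  name2acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(synonym_table))) {
    for (nm in synonym_table$gene_names[[i]]) {
      assign(nm, union(get0(nm, envir = name2acc, ifnotfound = character()),
                       synonym_table$accession[i]), envir = name2acc)
    }
  }
  list(acc2gene = acc2gene, name2acc = name2acc)
}

#' Assign the canonical gene symbol to a record
#'
#' Looks up the record's reported gene names in the synonym graph and sets
#' `canonical_gene` to the component's canonical name. When only accessions
#' are reported, the gene name is obtained through the offline synonym table
#' and then canonicalized. Unresolvable records are returned with status
#' `"unresolved"` rather than raising an error, so coverage can be reported.
#'
#' @param graph a [build_synonym_graph()] result
#' @param record an [identifier_record()]
#' @param synonym_table optional parsed table from [read_synonym_table()],
#'   needed when the record carries accessions only
#' @return the record with `canonical_gene` set (or attribute
#'   `status = "unresolved"`)
#' @export
canonicalize <- function(graph, record, synonym_table = NULL) {
  stopifnot(inherits(graph, "synonym_graph"),
            inherits(record, "identifier_record"))
  names_norm <- norm_gene_name(record$raw_gene_names)
  hit <- names_norm[names_norm %in% names(graph$canonical_map)]
  if (length(hit)) {
    record$canonical_gene <- unname(graph$canonical_map[[hit[1L]]])
    attr(record, "status") <- "resolved"
    return(record)
  }
  if (length(record$raw_accessions) && !is.null(synonym_table)) {
    maps <- synonym_table_maps(synonym_table)
    acc_hit <- record$raw_accessions[record$raw_accessions %in%
                                       names(maps$acc2gene)]
    if (length(acc_hit)) {
      gene <- unname(maps$acc2gene[[acc_hit[1L]]])
      if (gene %in% names(graph$canonical_map))
        gene <- unname(graph$canonical_map[[gene]])
      record$canonical_gene <- gene
      record$canonical_accession <- acc_hit[1L]
      attr(record, "status") <- "resolved"
      return(record)
    }
  }
  attr(record, "status") <- "unresolved"
  record
}

#' Detect non-synonymous names merged into one component
#'
#' Integration occasionally co-lists gene names that belong to different
#' proteins; the UniProt accessions then disagree. A component is flagged when
#' it contains two names whose accession sets are both non-empty and disjoint.
#' Flagged components are reported, never auto-split, mirroring a manual
#' curation step.
#'
#' @param graph a [build_synonym_graph()] result
#' @param accession_map named list: gene name -> character vector of accessions
#' @return data.frame with one row per conflicting component: `component`,
#'   `names` (comma-joined members with accessions), `canonical`
#' @export
detect_conflicts <- function(graph, accession_map) {
  stopifnot(inherits(graph, "synonym_graph"))
  names(accession_map) <- norm_gene_name(names(accession_map))
  out <- list()
  for (ci in seq_along(graph$components)) {
    members <- graph$components[[ci]]
    mapped <- members[members %in% names(accession_map)]
    mapped <- mapped[vapply(accession_map[mapped], length, 1L) > 0L]
    if (length(mapped) < 2L) next
    conflict <- FALSE
    for (i in seq_len(length(mapped) - 1L)) {
      for (j in seq(i + 1L, length(mapped))) {
        if (length(intersect(accession_map[[mapped[i]]],
                             accession_map[[mapped[j]]])) == 0L) {
          conflict <- TRUE
          break
        }
      }
      if (conflict) break
    }
    if (conflict) {
      out[[length(out) + 1L]] <- data.frame(
        component = ci,
        names = paste(mapped, collapse = ","),
        canonical = unname(graph$canonical_map[[members[1L]]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(component = integer(), names = character(),
               canonical = character(), stringsAsFactors = FALSE)
}

#' Fill missing gene names / accessions from the offline synonym table
#'
#' For every record missing its canonical gene or accession, attempts
#' resolution through the synonym table (accession -> gene and gene ->
#' accession). Unresolvable records are retained and counted.
#'
#' @param records list of [identifier_record()]s
#' @param synonym_table parsed table from [read_synonym_table()]
#' @return list with `records` (updated) and `report`
#'   (`resolved`/`unresolved` counts)
#' @export
fill_missing_identifiers <- function(records, synonym_table) {
  maps <- synonym_table_maps(synonym_table)
  resolved <- 0L
  unresolved <- 0L
  records <- lapply(records, function(rec) {
    stopifnot(inherits(rec, "identifier_record"))
    if (is.na(rec$canonical_gene)) {
      nm <- norm_gene_name(rec$raw_gene_names)
      if (length(nm)) {
        rec$canonical_gene <- nm[1L]
      } else {
        acc_hit <- rec$raw_accessions[rec$raw_accessions %in%
                                        names(maps$acc2gene)]
        if (length(acc_hit))
          rec$canonical_gene <- unname(maps$acc2gene[[acc_hit[1L]]])
      }
    }
    if (is.na(rec$canonical_accession)) {
      if (length(rec$raw_accessions)) {
        rec$canonical_accession <- rec$raw_accessions[1L]
      } else {
        for (nm in norm_gene_name(rec$raw_gene_names)) {
          acc <- get0(nm, envir = maps$name2acc, ifnotfound = character())
          if (length(acc)) {
            rec$canonical_accession <- acc[1L]
            break
          }
        }
      }
    }
    if (is.na(rec$canonical_gene) || is.na(rec$canonical_accession)) {
      unresolved <<- unresolved + 1L
    } else {
      resolved <<- resolved + 1L
    }
    rec
  })
  list(records = records,
       report = list(resolved = resolved, unresolved = unresolved))
}

#' Canonicalize a vector of gene labels
#'
#' Vectorized convenience wrapper over the synonym graph's canonical map:
#' labels present in the graph are replaced by their component's canonical
#' name; unknown labels are passed through uppercased.
#'
#' @param graph a [build_synonym_graph()] result
#' @param labels character vector of gene labels
#' @return character vector of canonical symbols
#' @export
canonical_labels <- function(graph, labels) {
  lab <- norm_gene_name(labels)
  hit <- lab %in% names(graph$canonical_map)
  lab[hit] <- unname(graph$canonical_map[lab[hit]])
  lab
}
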