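## Clade maps: named monophyletic groups over a set of terminal taxa.

#' Create a clade map
#'
#' A clade map names monophyletic groups (e.g. "Pentatomomorpha",
#' "Naboidea+Cimicoidea") as subsets of a terminal taxon set. It is the input
#' that tells [flag_synapomorphies()] which groups to scan.
#'
#' @param terminals Character vector of terminal taxon names.
#' @param clades Named list; each element a character vector of terminals.
#' @param ranks Optional data frame with columns `taxon`, `family`,
#'   `superfamily`, `infraorder`.
#' @return An object of class `clade_map`.
#' @export
clade_map <- function(terminals, clades, ranks = NULL) {
  terminals <- unique(as.character(terminals))
  stopifnot(is.list(clades))
  if (length(clades) > 0L) {
    if (is.null(names(clades)) || any(!nzchar(names(clades)))) {
      stop("all clades must be named", call. = FALSE)
    }
    check_unique_ids(names(clades))
    for (nm in names(clades)) {
      members <- unique(as.character(clades[[nm]]))
      if (length(members) == 0L) {
        stop("clade '", nm, "' is empty", call. = FALSE)
      }
      unknown <- setdiff(members, terminals)
      if (length(unknown) > 0L) {
        stop(
          "clade '", nm, "' references unknown terminal(s): ",
          paste(unknown, collapse = ", "),
          call. = FALSE
        )
      }
      clades[[nm]] <- members
    }
  }
  structure(
    list(terminals = terminals, clades = clades, ranks = ranks),
    class = "clade_map"
  )
}

#' @export
print.clade_map <- function(x, ...) {
  cat(sprintf(
    "<clade_map> %d terminals, %d named clades\n",
    length(x$terminals), length(x$clades)
  ))
  invisible(x)
}

#' Read a clade map from Newick or a rank table
#'
#' Two dialects are supported. A Newick tree with labeled internal nodes turns
#' each labeled node into a clade (its leaf set). A 4-column CSV
#' `taxon,family,superfamily,infraorder` turns each distinct rank value into a
#' clade. Compound clades such as `"Naboidea+Cimicoidea"` are declared via
#' `unions`: each entry `"X+Y"` defines a new clade as the union of already
#' defined clades `X` and `Y`.
#'
#' @param path Input path.
#' @param format `"newick"` or `"table"`; guessed from content when missing.
#' @param unions Character vector of `"X+Y"` union declarations.
#' @return A [clade_map()].
#' @export
read_clade_map <- function(path, format = NULL, unions = character(0)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(format)) {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^\\s*\\(", first)) "newick" else "table"
  }
  format <- match.arg(format, c("newick", "table"))
  cm <- if (format == "newick") {
    clade_map_from_newick(path)
  } else {
    clade_map_from_table(path)
  }
  add_clade_unions(cm, unions)
}

clade_map_from_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  clades <- list()
  if (!is.null(tree$node.label)) {
    n_tips <- length(tree$tip.label)
    for (k in seq_along(tree$node.label)) {
      lab <- tree$node.label[[k]]
      if (is.na(lab) || !nzchar(lab)) next
      node <- n_tips + k
      if (node == n_tips + 1L) {
        # root: all tips
        clades[[lab]] <- tree$tip.label
      } else {
        clades[[lab]] <- ape::extract.clade(tree, node)$tip.label
      }
    }
  }
  clade_map(tree$tip.label, clades)
}

clade_map_from_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("taxon", "family", "superfamily", "infraorder")
  if (!all(need %in% names(tab))) {
    stop(
      "clade table must have columns ", paste(need, collapse = ","),
      call. = FALSE
    )
  }
  check_unique_ids(tab$taxon)
  clades <- list()
  for (rank in c("family", "superfamily", "infraorder")) {
    vals <- unique(tab[[rank]])
    vals <- vals[!is.na(vals) & nzchar(vals)]
    for (v in vals) {
      if (!is.null(clades[[v]])) {
        stop("clade name '", v, "' appears at more than one rank", call. = FALSE)
      }
      clades[[v]] <- tab$taxon[!is.na(tab[[rank]]) & tab[[rank]] == v]
    }
  }
  clade_map(tab$taxon, clades, ranks = tab)
}

add_clade_unions <- function(cm, unions) {
  stopifnot(inherits(cm, "clade_map"))
  for (u in unions) {
    parts <- strsplit(u, "+", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop("union declaration must join >= 2 clades with '+': '", u, "'",
        call. = FALSE
      )
    }
    missing <- setdiff(parts, names(cm$clades))
    if (length(missing) > 0L) {
      stop(
        "union '", u, "' references undefined clade(s): ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    cm$clades[[u]] <- unique(unlist(cm$clades[parts], use.names = FALSE))
  }
  cm
}
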