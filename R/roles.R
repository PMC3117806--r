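# Role inference: solvents, reactants and products from linguistic context,
# and the reaction graph linking compound reference numbers.

SOLVENT_ACTIONS_DEFAULT <- c("Dissolve", "Wash", "Extract", "Quench",
                             "Partition")
STATE_MAP <- c(oil = "oil", oils = "oil", oily = "oil",
               solid = "solid", solids = "solid", powder = "solid",
               powders = "solid",
               crystal = "crystals", crystals = "crystals",
               needle = "crystals", needles = "crystals",
               gum = "gum", gums = "gum", foam = "foam", foams = "foam")
COLOUR_WORDS <- c("white", "yellow", "red", "orange", "brown", "black",
                  "green", "blue", "purple", "colourless", "colorless",
                  "pale")

#' Extract a compound reference number
#'
#' Chemists attach bold integers to compounds in synthesis write-ups; these
#' identifiers link reactants to products. For a character string (e.g. a
#' title line) the trailing integer is returned, in any accepted bold
#' dialect (\code{**82**}, \code{<b>82</b>}, or bare) with an optional
#' trailing colon. For a \code{MOLECULE} node, the reference leaf attached by
#' the parser (bold tag or bare integer in reference position) is returned.
#'
#' @param x a character string or a \code{phrase_node}.
#' @return integer reference number, or \code{NA_integer_} when absent.
#' @examples
#' extract_reference_number("5-Cyclobutyl-2,3-dihydro-[1H]-2-benzazepine 82:")
#' @export
extract_reference_number <- function(x) {
  UseMethod("extract_reference_number")
}

#' @export
extract_reference_number.character <- function(x) {
  if (length(x) != 1L || is.na(x)) return(NA_integer_)
  s <- trimws(x)
  m <- regmatches(s, regexec(
    "(?:\\*\\*([0-9]+)\\*\\*|<b>([0-9]+)</b>|\\b([0-9]+))\\s*:?\\s*$", s))[[1]]
  if (!length(m)) return(NA_integer_)
  digits <- m[-1][nzchar(m[-1])]
  if (!length(digits)) return(NA_integer_)
  as.integer(digits[1])
}

#' @export
extract_reference_number.phrase_node <- function(x) {
  leaves <- x$children
  seen_cm <- FALSE
  for (ch in leaves) {
    if (is_leaf(ch) && startsWith(ch$label, "OSCAR-")) seen_cm <- TRUE
    if (is_leaf(ch) && ch$label == "CD-BOLD") {
      return(as.integer(gsub("[^0-9]", "", ch$token$surface)))
    }
    if (is_leaf(ch) && ch$label == "CD" && seen_cm) {
      return(as.integer(ch$token$surface))
    }
  }
  NA_integer_
}

#' @export
extract_reference_number.default <- function(x) {
  if (is.null(x)) return(NA_integer_)
  stop("cannot extract a reference number from class ",
       paste(class(x), collapse = "/"))
}

.molecule_inventory <- function(trees) {
  rows <- list()
  visit <- function(node, anc_actions, prep_head, sentence) {
    if (identical(node$label, "ActionPhrase")) {
      anc_actions <- c(node$attrs$type, anc_actions)
    }
    if (identical(node$label, "PrepPhrase")) {
      prep_head <- .prep_surface(node)
    }
    if (identical(node$label, "MOLECULE")) {
      cm <- Filter(function(ch) is_leaf(ch) && startsWith(ch$label, "OSCAR-"),
                   node$children)
      sp <- node_span(node)
      rows[[length(rows) + 1L]] <<- list(
        surface = paste(vapply(cm, function(ch) ch$token$surface,
                               character(1)), collapse = " "),
        ref = extract_reference_number(node),
        prep_head = prep_head,
        actions = list(anc_actions),
        sentence = sentence, start = sp[1], end = sp[2])
    }
    for (ch in node$children) visit(ch, anc_actions, prep_head, sentence)
  }
  for (s in seq_along(trees)) {
    visit(trees[[s]], character(0), "", s)
  }
  rows
}

# Does any Yield phrase talk about "the title compound <ref>"?
.yield_title_ref <- function(trees) {
  for (tree in trees) {
    for (ap in find_nodes(tree, "ActionPhrase")) {
      if (!identical(ap$attrs$type, "Yield")) next
      toks <- ast_leaf_tokens(ap)
      low <- tolower(toks$surface)
      hit <- which(low == "title" & c(low[-1], "") == "compound")
      if (length(hit)) {
        after <- toks[(hit[1] + 2L):nrow(toks), , drop = FALSE]
        cand <- after[after$tag %in% c("CD-BOLD", "CD"), , drop = FALSE]
        if (nrow(cand)) {
          return(as.integer(gsub("[^0-9]", "", cand$surface[1])))
        }
      }
    }
  }
  NA_integer_
}

#' Infer compound roles from linguistic context
#'
#' Applies the role rules over a document of action-labelled sentence trees:
#' \describe{
#'   \item{R1 (solvent)}{a molecule inside a PrepPhrase headed by "in" or
#'     "with" within a Dissolve, Wash, Extract, Quench or Partition phrase.}
#'   \item{R2 (reactant)}{a molecule near the document start (the first
#'     \code{first_sentences} sentences) carrying a compound reference
#'     number.}
#'   \item{R3 (product)}{the title-line compound, corroborated when a Yield
#'     phrase mentions "the title compound" with the same reference number.}
#' }
#' Precedence on conflicts is R3 > R1 > R2; molecules matching no rule are
#' \code{unassigned}.
#'
#' @param trees list of action-labelled \code{Sentence} trees (the
#'   \code{tree} entries from [identify_actions()]).
#' @param title optional title line; its compound becomes the R3 candidate.
#' @param first_sentences how many leading sentences count as the document
#'   start for R2.
#' @param solvent_actions Action types whose in/with phrases mark solvents.
#' @return data.frame with columns \code{surface}, \code{role} (solvent,
#'   reactant, product or unassigned), \code{evidence}, \code{ref},
#'   \code{sentence}, \code{start}, \code{end}.
#' @export
assign_roles <- function(trees, title = NULL, first_sentences = 2L,
                         solvent_actions = SOLVENT_ACTIONS_DEFAULT) {
  if (inherits(trees, "phrase_node")) trees <- list(trees)
  inv <- .molecule_inventory(trees)
  out <- lapply(inv, function(m) {
    role <- "unassigned"
    evidence <- NA_character_
    acts <- m$actions[[1]]
    if (m$prep_head %in% c("in", "with") && any(acts %in% solvent_actions)) {
      role <- "solvent"
      evidence <- paste0("R1:", acts[acts %in% solvent_actions][1])
    } else if (!is.na(m$ref) && m$sentence <= first_sentences) {
      role <- "reactant"
      evidence <- "R2:start-of-text+reference-number"
    }
    data.frame(surface = m$surface, role = role, evidence = evidence,
               ref = m$ref, sentence = m$sentence, start = m$start,
               end = m$end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(data.frame(
    surface = character(0), role = character(0), evidence = character(0),
    ref = integer(0), sentence = integer(0), start = integer(0),
    end = integer(0), stringsAsFactors = FALSE))))
  if (!is.null(title)) {
    tref <- extract_reference_number(title)
    if (!is.na(tref)) {
      yref <- .yield_title_ref(trees)
      evidence <- if (!is.na(yref) && yref == tref) {
        "R3:title+yield-phrase"
      } else {
        "R3:title"
      }
      name <- trimws(sub(
        "(\\*\\*[0-9]+\\*\\*|<b>[0-9]+</b>|[0-9]+)\\s*:?\\s*$", "", title))
      out <- rbind(data.frame(
        surface = name, role = "product", evidence = evidence, ref = tref,
        sentence = 0L, start = NA_integer_, end = NA_integer_,
        stringsAsFactors = FALSE), out)
    }
  }
  rownames(out) <- NULL
  out
}

.product_state <- function(trees) {
  for (tree in trees) {
    for (ap in find_nodes(tree, "ActionPhrase")) {
      if (!identical(ap$attrs$type, "Yield")) next
      toks <- ast_leaf_tokens(ap)
      idx <- which(toks$tag == "NN-STATE")
      if (!length(idx)) next
      i <- idx[1]
      state <- STATE_MAP[tolower(toks$surface[i])]
      colour <- NA_character_
      if (i > 1L && tolower(toks$surface[i - 1L]) %in% COLOUR_WORDS) {
        colour <- tolower(toks$surface[i - 1L])
      }
      return(list(state = if (is.na(state)) "unknown" else unname(state),
                  colour = colour))
    }
  }
  list(state = "unknown", colour = NA_character_)
}

#' Build a reaction graph across preparations
#'
#' One node per distinct compound reference number; a directed edge from each
#' reactant to the product of the same preparation. Product nodes carry the
#' aggregation state extracted from the Yield phrase (unknown, solid, oil,
#' gum, foam, crystals) and, when present, the colour adjective preceding the
#' state word.
#'
#' @param docs a \code{chem_document} or list of them (one per preparation),
#'   see [chem_tag()].
#' @return list with \code{nodes} (data.frame: \code{ref}, \code{role},
#'   \code{state}, \code{colour}), \code{edges} (data.frame: \code{from},
#'   \code{to}) and \code{graph} (an \pkg{igraph} object).
#' @export
build_reaction_graph <- function(docs) {
  if (inherits(docs, "chem_document")) docs <- list(docs)
  nodes <- data.frame(ref = integer(0), role = character(0),
                      state = character(0), colour = character(0),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = integer(0), to = integer(0),
                      stringsAsFactors = FALSE)
  add_node <- function(ref, role, state = "unknown", colour = NA_character_) {
    if (ref %in% nodes$ref) {
      if (role == "product") {
        nodes$state[nodes$ref == ref] <<- state
        nodes$colour[nodes$ref == ref] <<- colour
        nodes$role[nodes$ref == ref] <<- role
      }
    } else {
      nodes[nrow(nodes) + 1L, ] <<- list(ref, role, state, colour)
    }
  }
  for (doc in docs) {
    stopifnot(inherits(doc, "chem_document"))
    roles <- doc$roles
    prod <- roles$ref[roles$role == "product" & !is.na(roles$ref)]
    reac <- unique(roles$ref[roles$role == "reactant" & !is.na(roles$ref)])
    if (!length(prod)) {
      warning("preparation without a product: edges omitted")
      for (r in reac) add_node(r, "reactant")
      next
    }
    st <- .product_state(doc$sentences)
    add_node(prod[1], "product", st$state, st$colour)
    for (r in reac) {
      add_node(r, "reactant")
      edges[nrow(edges) + 1L, ] <- list(r, prod[1])
    }
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$from),
                   to = as.character(edges$to)),
    directed = TRUE,
    vertices = if (nrow(nodes)) {
      data.frame(name = as.character(nodes$ref), role = nodes$role,
                 state = nodes$state,
                 colour = ifelse(is.na(nodes$colour), "", nodes$colour))
    } else NULL)
  list(nodes = nodes, edges = edges, graph = g)
}

#' Export a reaction graph as text files
#'
#' Writes tab-separated node and edge lists plus a GraphML file.
#'
#' @param rg result of [build_reaction_graph()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reaction_graph <- function(rg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  np <- file.path(dir, "nodes.tsv")
  ep <- file.path(dir, "edges.tsv")
  gp <- file.path(dir, "graph.graphml")
  write.table(rg$nodes, np, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(rg$edges, ep, sep = "\t", row.names = FALSE, quote = FALSE)
  igraph::write_graph(rg$graph, gp, format = "graphml")
  invisible(c(nodes = np, edges = ep, graphml = gp))
}
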