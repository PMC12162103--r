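#' Network specification
#'
#' A `tme_network` couples a node table (cell states and molecular species)
#' with a list of typed edges, the flux rules that connect them. Tumor cell
#' states may exist in two compartments, `exposed` (reachable by killer T
#' cells) and `protected` (behind the CAF barrier); all other nodes are
#' `global`.
#'
#' @param name node name (unique within a network).
#' @param role `"cell_state"` or `"molecular_species"`.
#' @param compartment `"exposed"`, `"protected"`, or `"global"`.
#' @return `node_spec()` returns a one-row data frame.
#' @export
node_spec <- function(name, role = c("cell_state", "molecular_species"),
                      compartment = c("global", "exposed", "protected")) {
  role <- match.arg(role)
  compartment <- match.arg(compartment)
  if (role == "molecular_species" && compartment != "global") {
    stop("molecular species must live in the global compartment")
  }
  data.frame(name = name, role = role, compartment = compartment,
             stringsAsFactors = FALSE)
}

EDGE_KINDS <- c("proliferation", "conversion", "paracrine",
                "regulatory_inhibition", "elimination", "death",
                "secretion", "degradation")

#' Typed edge of the flux network
#'
#' The `kind` selects the rate law; `params` names the registry entries the
#' edge consumes (see [flux-rules]). Kinds `paracrine`,
#' `regulatory_inhibition`, `elimination`, `secretion` and `conversion`
#' require a source node; `proliferation`, `death` and `degradation` act on
#' the target alone.
#'
#' @param kind one of `r paste(EDGE_KINDS, collapse = ", ")`.
#' @param target target node name.
#' @param source source node name (where the kind requires one).
#' @param params named character vector of registry parameter keys. The
#'   expected names depend on `kind`: `Kprol`; `Kconv` (plus optional extra
#'   rate keys whose product forms the rate); `Kpara`, `V`, optional
#'   `alpha`; `Vreg`, `alpha`; `Kkill`, optional `alpha_ac`; `KD`; `Ksec`.
#' @param site for `regulatory_inhibition`: which flux of the target the
#'   factor multiplies — `"proliferation"`, `"secretion"`, or
#'   `"elimination"` (the factor then scales every elimination flux whose
#'   killer is the target node).
#' @param gates for `conversion`: list of `list(species =, V =)` saturating
#'   occupancy factors `x/(V + x)` multiplying the conversion rate
#'   (mediating cytokines or co-requisite cell states).
#' @return an object of class `tme_edge`.
#' @export
edge_spec <- function(kind, target, source = NULL, params = character(),
                      site = NULL, gates = NULL) {
  kind <- match.arg(kind, EDGE_KINDS)
  needs_source <- kind %in% c("conversion", "paracrine",
                              "regulatory_inhibition", "elimination",
                              "secretion")
  if (needs_source && is.null(source)) {
    stop(sprintf("edge kind '%s' requires a source node", kind))
  }
  if (!needs_source && !is.null(source)) {
    stop(sprintf("edge kind '%s' takes no source node", kind))
  }
  if (kind == "regulatory_inhibition") {
    site <- match.arg(site, c("proliferation", "secretion", "elimination"))
  }
  structure(list(kind = kind, source = source, target = target,
                 params = params, site = site, gates = gates),
            class = "tme_edge")
}

#' Assemble a network specification
#'
#' @param nodes data frame with columns `name`, `role`, `compartment`
#'   (rows from [node_spec()]).
#' @param edges list of [edge_spec()] objects.
#' @param pools optional list of shared carrying-capacity pools:
#'   `list(members =, cap_key =)`. Members of a pool compete for one fixed
#'   resource capacity — their logistic terms all use
#'   `1 - sum(members) / capacity` (the resource-competition coupling: all
#'   six tumor compartments draw on one tumor resource supply).
#' @param protected_map named character vector mapping each exposed tumor
#'   node to its protected twin. Elimination fluxes against an exposed node
#'   are mirrored onto the twin scaled by [barrier_penetration()];
#'   first-order migration exchanges the pair toward the accessibility
#'   partition.
#' @param accessibility optional list naming the accessibility registry
#'   keys and the CAF node: `list(alpha =, Kbr =, delta =, caf =,
#'   mig_key =)`.
#' @return an object of class `tme_network`.
#' @export
network_spec <- function(nodes, edges, pools = NULL, protected_map = NULL,
                         accessibility = NULL) {
  stopifnot(is.data.frame(nodes),
            all(c("name", "role", "compartment") %in% names(nodes)))
  if (anyDuplicated(nodes$name)) {
    stop("node names must be unique within a network")
  }
  bad_comp <- nodes$role == "molecular_species" & nodes$compartment != "global"
  if (any(bad_comp)) stop("molecular species must be global")
  for (e in edges) {
    if (!inherits(e, "tme_edge")) stop("edges must be built with edge_spec()")
    for (nd in c(e$source, e$target)) {
      if (!nd %in% nodes$name) {
        stop(sprintf("edge (%s) references unknown node '%s'", e$kind, nd))
      }
    }
  }
  sig <- vapply(edges, function(e) {
    paste(e$kind, e$source %||% "", e$target, e$site %||% "")
  }, character(1))
  if (anyDuplicated(sig)) {
    stop(sprintf("duplicate flux definition: %s", sig[duplicated(sig)][1]))
  }
  structure(list(nodes = nodes, edges = edges, pools = pools,
                 protected_map = protected_map,
                 accessibility = accessibility),
            class = "tme_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tme_network <- function(x, ...) {
  cat(sprintf("tme_network: %d nodes (%d cell states, %d molecular), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "cell_state"),
              sum(x$nodes$role == "molecular_species"), length(x$edges)))
  invisible(x)
}

#' Count states and parameters
#'
#' @param network a [network_spec()].
#' @param params a named parameter vector (see [nominal_parameters()]).
#' @return integer vector `c(n_states, n_params)`.
#' @examples
#' counts <- count_states_params(build_hnscc_network(), nominal_parameters())
#' stopifnot(counts == c(24L, 91L))
#' @export
count_states_params <- function(network, params) {
  c(n_states = nrow(network$nodes), n_params = length(params))
}

#' Registry keys consumed by a network
#'
#' Every parameter name referenced by an edge, gate, capacity pool or the
#' accessibility block, deduplicated.
#'
#' @param network a [network_spec()].
#' @return character vector of registry keys.
#' @export
network_parameter_keys <- function(network) {
  keys <- unlist(lapply(network$edges, function(e) {
    c(e$params, vapply(e$gates %||% list(), `[[`, character(1), "V"))
  }))
  keys <- c(keys, vapply(network$pools %||% list(), `[[`, character(1),
                         "cap_key"))
  if (!is.null(network$accessibility)) {
    acc <- network$accessibility
    keys <- c(keys, acc$alpha, acc$Kbr, acc$delta, acc$mig_key)
  }
  unique(keys)
}

#' Validate a parameter set against a network
#'
#' Checks that every registry key consumed by an edge resolves, that all
#' values are finite and nonnegative, and that carrying capacities are
#' strictly positive.
#'
#' @inheritParams count_states_params
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_parameters <- function(network, params) {
  if (is.null(names(params)) || anyDuplicated(names(params))) {
    stop("parameters must be a uniquely named numeric vector")
  }
  if (any(!is.finite(params)) || any(params < 0)) {
    stop("all parameter values must be finite and >= 0")
  }
  for (e in network$edges) {
    missing <- setdiff(c(e$params, vapply(e$gates %||% list(), `[[`,
                                          character(1), "V")),
                       names(params))
    if (length(missing)) {
      stop(sprintf("edge %s -> %s (%s): unresolved parameter '%s'",
                   e$source %||% "-", e$target, e$kind, missing[1]))
    }
  }
  caps <- vapply(network$pools %||% list(), `[[`, character(1), "cap_key")
  missing <- setdiff(caps, names(params))
  if (length(missing)) {
    stop(sprintf("capacity pool: unresolved parameter '%s'", missing[1]))
  }
  if (length(caps) && any(params[caps] <= 0)) {
    stop("carrying capacities must be > 0")
  }
  invisible(TRUE)
}

#' Serialize a network
#'
#' `network_to_json()` writes the node/edge lists as JSON;
#' `network_to_graphml()` writes GraphML (nodes carry `role` and
#' `compartment` attributes, edges carry `kind` and their parameter keys;
#' requires the igraph package).
#'
#' @param network a [network_spec()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
network_to_json <- function(network, path) {
  edges <- lapply(network$edges, function(e) {
    list(kind = e$kind, source = e$source, target = e$target,
         params = as.list(e$params), site = e$site,
         gates = e$gates)
  })
  jsonlite::write_json(list(nodes = network$nodes, edges = edges),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname network_to_json
#' @export
network_to_graphml <- function(network, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export requires the igraph package")
  }
  edges <- Filter(function(e) !is.null(e$source), network$edges)
  el <- do.call(rbind, lapply(edges, function(e) {
    data.frame(from = e$source, to = e$target, kind = e$kind,
               parameter_keys = paste(e$params, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                     vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read and write parameter registries
#'
#' Flat key/value serialization of a parameter set, as JSON or YAML
#' (by file extension; YAML requires the yaml package).
#'
#' @param params named numeric vector.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_parameters()` the path invisibly; `read_parameters()` a
#'   named numeric vector.
#' @export
write_parameters <- function(params, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML output requires the yaml package")
    }
    yaml::write_yaml(as.list(params), path)
  } else {
    jsonlite::write_json(as.list(params), path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML input requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unlist(vals)
}
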