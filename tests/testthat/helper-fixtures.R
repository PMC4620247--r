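# Shared fixtures and independent brute-force oracles.  Populations are
# cached per (n, seed) so several test files can reuse them.

.fix <- new.env(parent = emptyenv())

fixture_registry <- function() {
  if (is.null(.fix$reg)) .fix$reg <- default_registry()
  .fix$reg
}

fixture_term <- function() {
  if (is.null(.fix$term)) .fix$term <- default_terminology()
  .fix$term
}

fixture_pop <- function(n, seed) {
  key <- sprintf("pop_%d_%d", n, seed)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- generate(generator_config(n_patients = n, seed = seed))
  }
  .fix[[key]]
}

cohort_of <- function(pop, members) {
  pop$patients[match(members$patient_id,
                     vapply(pop$patients, function(p) p$patient_id, ""))]
}

# hand-built canonical record
make_patient <- function(id = "T0001", sex = "F", birth = "1950-01-01",
                         registration = "1998-01-01", death = NA, transfer = NA,
                         conditions = NULL, observations = NULL) {
  conds <- if (is.null(conditions)) {
    data.frame(entry_id = character(0), code = character(0),
               code_system = character(0), start_date = as.Date(character(0)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(entry_id = sprintf("c%d", seq_len(nrow(conditions))),
               code = conditions$code,
               code_system = conditions$code_system %||% rep("ICD9CM", nrow(conditions)),
               start_date = as.Date(conditions$start_date),
               stringsAsFactors = FALSE)
  }
  obs <- if (is.null(observations)) {
    data.frame(entry_id = character(0), code = character(0),
               code_system = character(0), value = numeric(0), unit = character(0),
               date = as.Date(character(0)), stringsAsFactors = FALSE)
  } else {
    data.frame(entry_id = sprintf("o%d", seq_len(nrow(observations))),
               code = observations$code,
               code_system = rep("LOCAL-OBS", nrow(observations)),
               value = observations$value,
               unit = observations$unit %||% rep("mmHg", nrow(observations)),
               date = as.Date(observations$date), stringsAsFactors = FALSE)
  }
  structure(list(patient_id = id, sex = sex, birth_date = as.Date(birth),
                 registration_date = as.Date(registration),
                 death_date = as.Date(death), transfer_date = as.Date(transfer),
                 conditions = conds, observations = obs),
            class = "patient_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- brute-force oracles --------------------------------------------------

# reachability closure over symmetric exactMatch links, by repeated
# boolean matrix squaring (independent of the package's BFS)
bf_closure <- function(registry, element_id) {
  ids <- sort(names(registry$elements))
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (el in registry$elements) {
    for (lk in el$links) {
      if (lk$predicate == "exactMatch") {
        adj[el$id, lk$target] <- TRUE
        adj[lk$target, el$id] <- TRUE
      }
    }
  }
  reach <- adj
  repeat {
    nxt <- reach | (reach %*% adj > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  sort(ids[reach[element_id, ] & ids != element_id])
}

# all simple paths from `from` over symmetric exactMatch links, depth-first;
# feasible only on tiny registries (the path count grows factorially)
bf_all_paths <- function(registry, from) {
  adj <- list()
  for (el in registry$elements) {
    for (lk in el$links) {
      if (lk$predicate == "exactMatch") {
        adj[[el$id]] <- unique(c(adj[[el$id]], lk$target))
        adj[[lk$target]] <- unique(c(adj[[lk$target]], el$id))
      }
    }
  }
  paths <- list()
  walk <- function(path) {
    paths[[length(paths) + 1]] <<- path
    for (nb in adj[[path[length(path)]]] %||% character(0)) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  walk(from)
  paths
}

# minimal chain length reaching a spec for `cm`, by literal enumeration
bf_min_chain_length_enum <- function(registry, from, cm) {
  lens <- vapply(bf_all_paths(registry, from), function(p) {
    end <- p[length(p)]
    if (!is.null(registry$elements[[end]]$extraction_specs[[cm]])) length(p) else NA_integer_
  }, 1L)
  if (all(is.na(lens))) NA_integer_ else min(lens, na.rm = TRUE)
}

# minimal chain length via boolean matrix powers over the symmetric link
# matrix (reach-in-<=k-steps), independent of the package's queue BFS
bf_min_chain_length <- function(registry, from, cm) {
  ids <- sort(names(registry$elements))
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(adj) <- TRUE
  for (el in registry$elements) {
    for (lk in el$links) {
      if (lk$predicate == "exactMatch") {
        adj[el$id, lk$target] <- TRUE
        adj[lk$target, el$id] <- TRUE
      }
    }
  }
  has_spec <- vapply(ids, function(id)
    !is.null(registry$elements[[id]]$extraction_specs[[cm]]), TRUE)
  reach <- stats::setNames(ids == from, ids)
  for (k in 0:n) {
    if (any(reach & has_spec)) return(k + 1L)
    reach <- (adj %*% reach) > 0
    reach <- stats::setNames(as.vector(reach), ids)
  }
  NA_integer_
}

# naive basic-graph-pattern matcher: enumerate every assignment of the
# pattern variables to terms occurring in the graph
bf_match_bgp <- function(triples, query) {
  vars <- unique(unlist(lapply(query$patterns, function(p) p[grepl("^\\?", p)])))
  terms <- unique(c(triples$s, triples$p, triples$o))
  trip_key <- paste(triples$s, triples$p, triples$o, sep = "\r")
  grid <- do.call(expand.grid, c(stats::setNames(
    rep(list(terms), length(vars)), vars), stringsAsFactors = FALSE))
  ok <- rep(TRUE, nrow(grid))
  for (pat in query$patterns) {
    inst <- lapply(pat, function(tm) {
      if (grepl("^\\?", tm)) grid[[tm]] else rep(tm, nrow(grid))
    })
    ok <- ok & (paste(inst[[1]], inst[[2]], inst[[3]], sep = "\r") %in% trip_key)
  }
  sol <- grid[ok, , drop = FALSE]
  for (v in names(query$filters)) {
    if (v %in% names(sol)) sol <- sol[sol[[v]] == query$filters[[v]], , drop = FALSE]
  }
  sol <- unique(sol)
  proj <- query$vars
  for (mv in setdiff(proj, names(sol))) sol[[mv]] <- rep(NA_character_, nrow(sol))
  out <- sol[, proj, drop = FALSE]
  names(out) <- substring(proj, 2)
  rownames(out) <- NULL
  out
}

sorted_rows <- function(df) {
  if (!nrow(df)) return(df)
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# independent eligibility re-application: straight vectorized rules over
# the canonical records with hard-coded warehouse code sets
BF_ACS_CODES <- c("410.0", "410.1", "410.9", "411.1")

bf_eligibility <- function(patients) {
  verdict <- character(length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    hit <- p$conditions$code %in% BF_ACS_CODES & p$conditions$code_system == "ICD9CM"
    if (!any(hit)) { verdict[i] <- "no_first_acs_in_window"; next }
    acs <- min(p$conditions$start_date[hit])
    if (acs < as.Date("2005-01-01") || acs > as.Date("2011-12-31")) {
      verdict[i] <- "no_first_acs_in_window"; next
    }
    if (p$registration_date > acs - 365) { verdict[i] <- "insufficient_history"; next }
    if (!is.na(p$death_date) && p$death_date <= acs + 30) {
      verdict[i] <- "death_within_30_days"; next
    }
    age <- length(seq(p$birth_date, acs, by = "year")) - 1L
    if (age < 18) { verdict[i] <- "under_min_age"; next }
    verdict[i] <- "member"
  }
  verdict
}

# random small registry for link-traversal property tests
random_registry <- function(n_elements, seed, cm = "CM-T", spec_prob = 0.3,
                            link_prob = 0.15) {
  set.seed(seed)
  ids <- sprintf("R:E%02d", seq_len(n_elements))
  elements <- lapply(seq_len(n_elements), function(i) {
    links <- list()
    for (j in seq_len(n_elements)) {
      if (j != i && stats::runif(1) < link_prob) {
        links[[length(links) + 1]] <- list(predicate = "exactMatch", target = ids[j])
      }
    }
    specs <- if (stats::runif(1) < spec_prob) {
      list(list(content_model = cm, dialect = "path", script = "/x/@v", anchor = "entry"))
    } else list()
    list(id = ids[i], name = ids[i], object_class = "R:C",
         value_domain = list(datatype = "text"),
         extraction_specs = specs, links = links)
  })
  load_registry(list(registries = list(list(registry_id = "R", elements = elements))))
}

# random triple graph + random BGP query for extraction property tests
random_graph_case <- function(seed) {
  set.seed(seed)
  nodes <- paste0("<urn:n", 1:4, ">")
  preds <- paste0("<urn:p", 1:3, ">")
  lits <- c("\"a\"", "\"b\"")
  nt <- sample(4:12, 1)
  triples <- unique(data.frame(
    s = sample(nodes, nt, replace = TRUE),
    p = sample(preds, nt, replace = TRUE),
    o = sample(c(nodes, lits), nt, replace = TRUE),
    stringsAsFactors = FALSE))
  np <- sample(1:3, 1)
  vars <- c("?entry", "?value", "?w")
  patterns <- lapply(seq_len(np), function(k) {
    c(sample(c(nodes, vars[1]), 1),
      sample(preds, 1),
      sample(c(nodes, lits, vars[2:3]), 1))
  })
  used <- intersect(vars, unlist(patterns))
  if (!length(used)) {
    patterns[[1]][1] <- "?entry"
    used <- "?entry"
  }
  filters <- character(0)
  if ("?value" %in% used && stats::runif(1) < 0.3) filters["?value"] <- "\"a\""
  list(triples = triples,
       query = list(vars = used, patterns = patterns, filters = filters))
}
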