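# Deterministic synthetic sources and brute-force oracles --------------------
#
# Everything here is a pure function of its parameters and seed, so every
# pipeline stage is testable offline. The expected outputs bundled with each
# generator are computed by straightforward independent code (nested-loop
# joins, direct tree construction), never by the engines under test.

with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# -- random document trees ---------------------------------------------------

FIX_NAMES <- c("a", "b", "c", "name", "value", "id", "title", "meta",
               "entry", "rev", "date", "row", "item", "@num", "@id",
               "@type", "_$", "x", "y", "keywords")

#' Generate a random document tree
#'
#' Shapes mirror records arriving from XML/CSV/JSON conversion: objects with
#' unique member names (including `@`-attribute and `_$`-text names), arrays
#' of scalars or of objects (arrays never nest directly inside arrays, and
#' are never empty — repeated XML members always carry at least one element),
#' string/number/boolean scalars.
#'
#' @param max_depth maximum nesting depth (0 gives a scalar).
#' @param max_fanout maximum members per object / elements per array.
#' @param seed RNG seed.
#' @return a document tree.
#' @export
gen_random_tree <- function(max_depth = 4L, max_fanout = 4L, seed = 1L) {
  with_rng_seed(seed, gen_tree_rec(max_depth, max_fanout, in_array = FALSE))
}

gen_scalar <- function() {
  k <- sample(3L, 1L, prob = c(0.7, 0.2, 0.1))
  if (k == 1L) {
    paste0(sample(c(letters, 0:9), sample(1:8, 1L), replace = TRUE),
           collapse = "")
  } else if (k == 2L) {
    sample(0:999, 1L)
  } else {
    sample(c(TRUE, FALSE), 1L)
  }
}

gen_tree_rec <- function(depth, fanout, in_array) {
  if (depth <= 0L) return(gen_scalar())
  kind <- sample(c("object", "array", "scalar"), 1L,
                 prob = if (in_array) c(0.8, 0, 0.2) else c(0.5, 0.25, 0.25))
  if (kind == "scalar") return(gen_scalar())
  n <- sample(seq_len(fanout), 1L)
  if (kind == "object") {
    nms <- sample(FIX_NAMES, n)
    out <- tree_object()
    for (nm in nms) {
      out[[nm]] <- gen_tree_rec(depth - 1L, fanout, in_array = FALSE)
    }
    return(out)
  }
  # array: homogeneous scalars or objects, never empty
  if (runif(1) < 0.4) {
    return(lapply(seq_len(n), function(i) gen_scalar()))
  }
  lapply(seq_len(n), function(i) {
    gen_tree_rec(depth - 1L, fanout, in_array = TRUE)
  })
}

#' Generate a random source path, biased toward matching a given tree
#'
#' Builds a path by randomly walking the tree's actual member names,
#' occasionally inserting deep scans, wildcards, indices and filters, and
#' occasionally mutating a name so absent-path behaviour is exercised too.
#'
#' @param tree the tree to aim at.
#' @param seed RNG seed.
#' @return a `jp_source_path`.
#' @export
gen_random_path <- function(tree, seed = 1L) {
  with_rng_seed(seed, {
    parts <- character(0)
    node <- tree
    steps <- sample(1:4, 1L)
    for (k in seq_len(steps)) {
      if (is_tree_array(node)) {
        if (runif(1) < 0.5 && length(parts) > 0L) {
          parts[length(parts)] <- paste0(parts[length(parts)],
            if (runif(1) < 0.6) "[*]"
            else paste0("[", sample(seq_along(node), 1L) - 1L, "]"))
        }
        node <- node[[sample(seq_along(node), 1L)]]
      }
      if (!is_tree_object(node) || length(node) == 0L) break
      nm <- sample(names(node), 1L)
      sep <- if (runif(1) < 0.25) ".." else "."
      parts <- c(parts, paste0(sep, "'", nm, "'"))
      node <- node[[nm]]
    }
    if (length(parts) == 0L) parts <- ".'a'"
    if (runif(1) < 0.15) {
      # mutate one name so some paths miss
      i <- sample(seq_along(parts), 1L)
      parts[i] <- sub("'([^']+)'", "'zz\\1'", parts[i])
    }
    if (runif(1) < 0.2 && is_tree_array(node) &&
        all(vapply(node, is_tree_object, logical(1)))) {
      cand <- names(node[[1L]])
      cand <- cand[vapply(node[[1L]][cand], is_tree_scalar, logical(1))]
      if (length(cand)) {
        nm <- sample(cand, 1L)
        parts[length(parts)] <- paste0(parts[length(parts)],
          "[?(@.'", nm, "' = '", scalar_text(node[[1L]][[nm]]), "')]")
      }
    }
    parse_source_path(paste0("$", paste(parts, collapse = "")))
  })
}

# -- brute-force path oracle -------------------------------------------------

#' Exhaustive reference matcher for source paths
#'
#' Deliberately simple and slow: each step maps a candidate set to the next
#' by direct case analysis of the step definition, with deep scan enumerated
#' by a full subtree walk. Kept independent of the production matcher so the
#' two can be compared on random inputs.
#'
#' @param tree a document tree.
#' @param path a `jp_source_path` (or path text).
#' @return list of matches (`value`, `location`), document order.
#' @export
brute_force_match <- function(tree, path) {
  if (is.character(path)) path <- parse_source_path(path)

  enumerate_subnodes <- function(node, loc) {
    # every node in the subtree, preorder, with its location
    acc <- list(list(value = node, location = loc))
    if (is.list(node)) {
      nms <- names(node)
      for (i in seq_along(node)) {
        stp <- if (is.null(nms)) i - 1L else nms[[i]]
        acc <- c(acc, enumerate_subnodes(node[[i]], c(loc, list(stp))))
      }
    }
    acc
  }

  take_member <- function(cand, nm) {
    out <- list()
    v <- cand$value
    if (is.list(v) && !is.null(names(v)) && nm %in% names(v)) {
      out <- list(list(value = v[[nm]], location = c(cand$location, list(nm))))
    } else if (is.list(v) && is.null(names(v))) {
      for (i in seq_along(v)) {
        el <- v[[i]]
        if (is.list(el) && !is.null(names(el)) && nm %in% names(el)) {
          out[[length(out) + 1L]] <-
            list(value = el[[nm]],
                 location = c(cand$location, list(i - 1L, nm)))
        }
      }
    }
    out
  }

  pred_holds <- function(node, op) {
    v <- node
    for (nm in op$rel) {
      if (!(is.list(v) && !is.null(names(v)) && nm %in% names(v))) return(FALSE)
      v <- v[[nm]]
    }
    if (!(is.atomic(v) && length(v) == 1L)) return(FALSE)
    same <- identical(scalar_text(v), op$literal)
    if (op$op == "eq") same else !same
  }

  apply_op <- function(cands, op) {
    out <- list()
    for (cand in cands) {
      v <- cand$value
      is_arr <- is.list(v) && is.null(names(v))
      if (op$kind == "wildcard") {
        if (is_arr) {
          for (i in seq_along(v)) {
            out[[length(out) + 1L]] <-
              list(value = v[[i]], location = c(cand$location, list(i - 1L)))
          }
        } else out[[length(out) + 1L]] <- cand
      } else if (op$kind == "index") {
        if (is_arr) {
          if (op$i + 1L <= length(v)) {
            out[[length(out) + 1L]] <-
              list(value = v[[op$i + 1L]],
                   location = c(cand$location, list(op$i)))
          }
        } else if (op$i == 0L) out[[length(out) + 1L]] <- cand
      } else { # filter
        if (is_arr) {
          for (i in seq_along(v)) {
            if (pred_holds(v[[i]], op)) {
              out[[length(out) + 1L]] <-
                list(value = v[[i]], location = c(cand$location, list(i - 1L)))
            }
          }
        } else if (pred_holds(v, op)) out[[length(out) + 1L]] <- cand
      }
    }
    out
  }

  cands <- list(list(value = tree, location = list()))
  for (st in path$steps) {
    nxt <- list()
    for (cand in cands) {
      if (st$kind == "child") {
        nxt <- c(nxt, take_member(cand, st$name))
      } else {
        for (sub in enumerate_subnodes(cand$value, cand$location)) {
          if (is.list(sub$value) && !is.null(names(sub$value)) &&
              st$name %in% names(sub$value)) {
            nxt[[length(nxt) + 1L]] <-
              list(value = sub$value[[st$name]],
                   location = c(sub$location, list(st$name)))
          }
        }
      }
    }
    for (op in st$ops) nxt <- apply_op(nxt, op)
    cands <- nxt
  }
  cands
}

# -- mock three-endpoint REST source -----------------------------------------

xml_esc <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

leaf <- function(x) tree_object(`_$` = x)

#' Mock three-endpoint web-service source with its expected join output
#'
#' Emulates a project / subject / subject-detail REST source: a project list
#' document, a subject list document (each subject carrying its project id),
#' and a per-subject detail endpoint addressed by a `${sid}` URL template.
#' The bundled ingestion script retrieves all three, partitions the first
#' two into records and three-way inner-joins them; `expected` holds the
#' joined records computed here by a plain nested-loop join.
#'
#' @param n_projects,n_subjects_per_project fixture cardinalities.
#' @param seed RNG seed for the pseudo-random record content.
#' @param mutate_sid optional subject id whose detail content is altered
#'   (for update-detection tests).
#' @return list with `routes`, `script`, `descriptor`, `expected` (list of
#'   joined trees), `subject_ids`, and `detail_url_template`.
#' @export
gen_three_service_source <- function(n_projects = 3L,
                                     n_subjects_per_project = 4L,
                                     seed = 7L, mutate_sid = NULL) {
  with_rng_seed(seed, {
    base <- "http://mock.local"
    projects <- lapply(seq_len(n_projects), function(i) {
      list(pid = paste0("P", i),
           title = paste0("Study-", paste0(sample(letters, 6), collapse = "")))
    })
    subjects <- list()
    for (p in projects) {
      for (j in seq_len(n_subjects_per_project)) {
        subjects[[length(subjects) + 1L]] <-
          list(sid = paste0(p$pid, "S", j), pid = p$pid,
               age = sample(18:80, 1L))
      }
    }
    details <- lapply(subjects, function(s) {
      list(sid = s$sid,
           handedness = sample(c("left", "right"), 1L),
           score = sample(1:100, 1L))
    })
    names(details) <- vapply(subjects, `[[`, character(1), "sid")
    if (!is.null(mutate_sid)) {
      if (!mutate_sid %in% names(details)) {
        stop_record("no such subject id: ", mutate_sid)
      }
      details[[mutate_sid]]$score <- details[[mutate_sid]]$score + 1000L
      details[[mutate_sid]]$handedness <- "ambidextrous"
    }

    proj_xml <- paste0(
      "<rows>",
      paste(vapply(projects, function(p) {
        paste0("<row><pid>", p$pid, "</pid><title>", xml_esc(p$title),
               "</title></row>")
      }, character(1)), collapse = ""),
      "</rows>")
    subj_xml <- paste0(
      "<rows>",
      paste(vapply(subjects, function(s) {
        paste0("<row><sid>", s$sid, "</sid><pid>", s$pid, "</pid><age>",
               s$age, "</age></row>")
      }, character(1)), collapse = ""),
      "</rows>")
    detail_xml <- lapply(details, function(d) {
      paste0("<subject><sid>", d$sid, "</sid><handedness>", d$handedness,
             "</handedness><score>", d$score, "</score></subject>")
    })

    routes <- list()
    routes[[paste0(base, "/projects")]] <- proj_xml
    routes[[paste0(base, "/subjects")]] <- subj_xml
    for (sid in names(detail_xml)) {
      routes[[paste0(base, "/subject/", sid)]] <- detail_xml[[sid]]
    }

    script <- paste(
      paste0('DOWNLOAD "', base, '/projects" TO projDl FORMAT xml;'),
      paste0('DOWNLOAD "', base, '/subjects" TO subjDl FORMAT xml;'),
      paste0('DOWNLOAD "', base, '/subject/${sid}" TO detail FORMAT xml;'),
      'PARTITION projects = projDl ON "rows.row";',
      'PARTITION subjects = subjDl ON "rows.row";',
      paste0('JOIN ps = projects TO subjects ON "$.\'pid\'.\'_$\'" = ',
             '"$.\'pid\'.\'_$\'";'),
      paste0('JOIN full = ps TO detail ON "$.\'subjects\'.\'sid\'.\'_$\'" = ',
             '"$.\'sid\'.\'_$\'";'),
      "INGEST full;",
      sep = "\n")

    descriptor <- source_descriptor(
      source_id = "mock-three-service", name = "Mock three-endpoint source",
      ingest_method = "dsl",
      params = list(script = script,
                    primaryKeyPath = "$.'subjects'.'sid'.'_$'"))

    # expected join output: plain nested loops over the generated content
    expected <- list()
    for (p in projects) {
      for (s in subjects) {
        if (!identical(s$pid, p$pid)) next
        d <- details[[s$sid]]
        rec <- tree_object(pid = leaf(p$pid), title = leaf(xml_esc(p$title)))
        rec[["subjects"]] <- tree_object(sid = leaf(s$sid), pid = leaf(s$pid),
                                         age = leaf(as.character(s$age)))
        rec[["detail"]] <- tree_object(
          sid = leaf(d$sid), handedness = leaf(d$handedness),
          score = leaf(as.character(d$score)))
        expected[[length(expected) + 1L]] <- rec
      }
    }

    list(routes = routes, script = script, descriptor = descriptor,
         expected = expected,
         subject_ids = names(detail_xml),
         detail_url_template = paste0(base, "/subject/${sid}"))
  })
}

#' Write the mock endpoint documents into a directory (file:// rendering)
#'
#' @param fixture result of [gen_three_service_source()].
#' @param dir output directory.
#' @return named vector mapping mock URLs to `file://` URLs.
#' @export
write_mock_source_dir <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (url in names(fixture$routes)) {
    fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9]", "_", url), ".xml"))
    writeLines(fixture$routes[[url]], fn, sep = "")
    out[[url]] <- paste0("file://", normalizePath(fn))
  }
  out
}

# -- PDB-like records exercising every transformation statement --------------

#' PDB-like nested XML records with independently computed expectations
#'
#' Each record exercises every transformation-statement type: an entry id,
#' a revision list with `@num` attributes and release dates, comma-separated
#' keyword strings, source/host taxonomy ids, organism name/type pairs (one
#' `scientific`), an EVA-style name/value metadata block and a
#' `SourceAccession` that alternates GEO-style (`GSE...`) and other
#' accessions. `expected` is built by direct construction from the drawn
#' values — a straight-line reference evaluator independent of the engine.
#'
#' @param n number of records.
#' @param seed RNG seed.
#' @return list of `list(xml=, tree=, expected=)`, plus the script under
#'   attribute `"script"` (see [pdb_like_script()]).
#' @export
gen_pdb_like_records <- function(n = 5L, seed = 1L) {
  recs <- with_rng_seed(seed, lapply(seq_len(n), function(i) {
    entry_id <- paste0(i, paste0(sample(LETTERS, 3), collapse = ""))
    date1 <- sprintf("%d-%02d-%02d", sample(1995:2015, 1),
                     sample(1:12, 1), sample(1:28, 1))
    date2 <- "2020-01-01"
    kw1 <- paste(sample(c("TRANSFERASE", "KINASE", "HYDROLASE", "LYASE"),
                        2), collapse = ", ")
    kw2 <- paste(sample(c("ATP-BINDING", "PHOSPHORYLATION", "METAL-BINDING"),
                        2), collapse = ", ")
    tax_src <- as.character(sample(c(9606, 10090, 10116, 7227), 1))
    tax_host <- as.character(sample(c(562, 4932), 1))
    sci_name <- sample(c("Homo sapiens", "Mus musculus", "Rattus norvegicus"),
                       1)
    common_name <- sample(c("human", "mouse", "rat"), 1)
    eva <- list(species = sample(c("rat", "mouse"), 1),
                region = sample(c("CA1", "CA3", "DG"), 1))
    accession <- if (i %% 2L == 1L) paste0("GSE", 1000 + i)
                 else paste0("SRP", 1000 + i)

    xml <- paste0(
      '<record xmlns:PDBx="http://pdbml.pdb.org/schema">',
      '<PDBx:datablock datablockName="', entry_id, '">',
      '<PDBx:atom_sites entry_id="', entry_id, '"/>',
      "<PDBx:database_PDB_revCategory>",
      '<PDBx:database_PDB_rev num="1"><PDBx:date>', date1,
      "</PDBx:date></PDBx:database_PDB_rev>",
      '<PDBx:database_PDB_rev num="2"><PDBx:date>', date2,
      "</PDBx:date></PDBx:database_PDB_rev>",
      "</PDBx:database_PDB_revCategory>",
      "<PDBx:struct_keywords>",
      "<PDBx:pdbx_keywords>", kw1, "</PDBx:pdbx_keywords>",
      "<PDBx:text>", kw2, "</PDBx:text>",
      "</PDBx:struct_keywords>",
      "<PDBx:entity_src_genCategory>",
      "<PDBx:entity_src_gen>",
      "<PDBx:pdbx_gene_src_ncbi_taxonomy_id>", tax_src,
      "</PDBx:pdbx_gene_src_ncbi_taxonomy_id>",
      "<PDBx:pdbx_host_org_ncbi_taxonomy_id>", tax_host,
      "</PDBx:pdbx_host_org_ncbi_taxonomy_id>",
      "</PDBx:entity_src_gen>",
      "</PDBx:entity_src_genCategory>",
      "</PDBx:datablock>",
      "<entry><organism>",
      '<name type="common">', common_name, "</name>",
      '<name type="scientific">', sci_name, "</name>",
      "</organism></entry>",
      "<metadata><name>species</name><value>", eva$species,
      "</value></metadata>",
      "<metadata><name>region</name><value>", eva$region,
      "</value></metadata>",
      "<SourceAccession>", accession, "</SourceAccession>",
      "</record>")

    split_kw <- function(s) strsplit(s, "\\s*,\\s*", perl = TRUE)[[1]]
    expected <- tree_object(
      dataRepository = tree_object(name = "Protein Data Bank"),
      access = tree_object(
        landingPage = paste0(
          "http://www.rcsb.org/pdb/explore/explore.do?structureId=",
          entry_id)),
      dataset = tree_object(
        dateReleased = paste0(date1, "T00:00:00"),
        keywords = lapply(c(split_kw(kw1), split_kw(kw2)), identity)),
      taxonomicInformation = list(
        tree_object(ID = paste0("ncbitax:", tax_src), name = sci_name),
        tree_object(ID = paste0("ncbitax:", tax_host))),
      metadata = tree_object(species = eva$species, region = eva$region)
    )
    if (startsWith(accession, "GSE")) {
      expected[["datasetDistributions"]] <- list(
        tree_object(), tree_object(),
        tree_object(storedIn = "Gene Expression Omnibus"))
    }
    list(xml = xml, tree = xml_to_tree(xml), expected = expected)
  }))
  attr(recs, "script") <- pdb_like_script()
  recs
}

#' The transformation script applied to the PDB-like fixture records
#'
#' One statement per statement type: constant generation, landing-page
#' concatenation, pattern-based date normalization, keyword splitting over
#' two columns, taxonomy-id union into CURIEs, scientific-name join with
#' empty-string fallback, EVA name/value reification, and a conditional
#' constant keyed on a `%GSE%` accession pattern.
#'
#' @return script text.
#' @export
pdb_like_script <- function() {
  paste(
    'let "dataRepository.name" = "Protein Data Bank";',
    paste0('transform column "$.\'PDBx:datablock\'.\'PDBx:atom_sites\'',
           '.\'@entry_id\'" to "access.landingPage" apply ',
           "{{ result ='http://www.rcsb.org/pdb/explore/explore.do",
           "?structureId=' + value}};"),
    paste0('transform column "$..\'PDBx:database_PDB_revCategory\'',
           ".'PDBx:database_PDB_rev'[?(@.'@num' = '1')].'PDBx:date'",
           '.\'_$\'" to "dataset.dateReleased" apply ',
           'toStandardDateTime("yyyy-MM-dd");'),
    paste0('transform columns "$..\'PDBx:struct_keywords\'',
           '.\'PDBx:pdbx_keywords\'.\'_$\'", ',
           '"$..\'PDBx:struct_keywords\'.\'PDBx:text\'.\'_$\'" ',
           'to "dataset.keywords[]" apply {{',
           '\narr=re.split("\\s*,\\s*",value1,)',
           '\narr.extend(re.split("\\s*,\\s*",value2))',
           "\nresult=arr\n}};"),
    paste0('transform union "$..\'PDBx:entity_src_gen\'',
           '.\'PDBx:pdbx_gene_src_ncbi_taxonomy_id\'.\'_$\'", ',
           '"$..\'PDBx:entity_src_gen\'',
           '.\'PDBx:pdbx_host_org_ncbi_taxonomy_id\'.\'_$\'" ',
           'to "taxonomicInformation[].ID" ',
           "apply {{ result = 'ncbitax:' + value }};"),
    paste0('join "$.\'entry\'.\'organism\'.\'name\'[*].\'@type\'", ',
           '"$.\'entry\'.\'organism\'.\'name\'[*].\'_$\'" ',
           'to "taxonomicInformation[0].name" apply {{',
           "\ni = -1",
           "\ntry:",
           "\n    i = value1.index('scientific')",
           "\nexcept:",
           "\n    pass",
           "\nresult = value2[i] if i >= 0 else ''",
           "\n}};"),
    paste0('transform column "$.\'metadata\'[*].\'value\'.\'_$\'" ',
           'to "metadata.value" ',
           'assign name from "$.\'metadata\'[*].\'name\'.\'_$\'";'),
    paste0('if "$.\'SourceAccession\'.\'_$\'" like "%GSE%" then ',
           'let "datasetDistributions[2].storedIn" = ',
           '"Gene Expression Omnibus";'),
    sep = "\n")
}
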