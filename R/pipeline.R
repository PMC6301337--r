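# Message-driven pipeline orchestration --------------------------------------
#
# A dispatcher routes (docId, status) messages through a status->queue route
# table derived from the configured workflow; consumer containers host one
# execution lane per configured consumer. The reference broker is in-process
# with lease-based redelivery: a taken-but-unacked message returns to its
# queue when its lease expires (simulated clock), which is how crashed
# consumers are survived. Delivery is at-least-once; effects are idempotent
# because wrapper writes are keyed by (docId, status).

#' In-process message broker with lease-based redelivery
#'
#' Named FIFO queues with at-least-once delivery: `take()` leases a message
#' to the caller; `ack()` completes it; an expired lease (or a consumer that
#' never acks) puts the message back on its queue. An optional journal file
#' records every put/ack for post-run accounting.
#'
#' @export
Broker <- R6::R6Class("Broker",
  public = list(
    #' @field lease_ticks clock ticks before an unacked lease is redelivered.
    lease_ticks = NULL,
    #' @field puts,acks,redeliveries counters.
    puts = 0L, acks = 0L, redeliveries = 0L,
    #' @description Create a broker.
    #' @param lease_ticks lease duration in clock ticks.
    #' @param journal optional path; every put/ack is appended as a line.
    initialize = function(lease_ticks = 5L, journal = NULL) {
      private$queues <- new.env(parent = emptyenv())
      private$leases <- list()
      private$clock <- 0
      self$lease_ticks <- lease_ticks
      private$journal <- journal
    },
    #' @description Append a message to a queue.
    #' @param queue queue name.
    #' @param msg `list(doc_id=, status=)`.
    put = function(queue, msg) {
      q <- private$get_queue(queue)
      q[[length(q) + 1L]] <- msg
      assign(queue, q, envir = private$queues)
      self$puts <- self$puts + 1L
      private$log("PUT", queue, msg)
      invisible(NULL)
    },
    #' @description Lease the head message of a queue (NULL if empty).
    #' @param queue queue name.
    take = function(queue) {
      q <- private$get_queue(queue)
      if (length(q) == 0L) return(NULL)
      msg <- q[[1L]]
      assign(queue, q[-1L], envir = private$queues)
      private$lease_n <- private$lease_n + 1L
      id <- paste0("L", private$lease_n)
      private$leases[[id]] <- list(queue = queue, msg = msg,
                                   expires = private$clock + self$lease_ticks)
      msg$lease_id <- id
      msg
    },
    #' @description Acknowledge a leased message.
    #' @param lease_id the lease id attached by `take()`.
    ack = function(lease_id) {
      if (is.null(private$leases[[lease_id]])) return(invisible(FALSE))
      private$log("ACK", private$leases[[lease_id]]$queue,
                  private$leases[[lease_id]]$msg)
      private$leases[[lease_id]] <- NULL
      self$acks <- self$acks + 1L
      invisible(TRUE)
    },
    #' @description Advance the simulated clock; expired leases requeue.
    #' @param dt ticks to advance.
    tick = function(dt = 1) {
      private$clock <- private$clock + dt
      expired <- names(private$leases)[vapply(private$leases, function(l) {
        l$expires <= private$clock
      }, logical(1))]
      for (id in expired) {
        l <- private$leases[[id]]
        private$leases[[id]] <- NULL
        q <- private$get_queue(l$queue)
        q[[length(q) + 1L]] <- l$msg
        assign(l$queue, q, envir = private$queues)
        self$redeliveries <- self$redeliveries + 1L
      }
      invisible(length(expired))
    },
    #' @description Number of queued messages (one queue or all).
    #' @param queue optional queue name.
    size = function(queue = NULL) {
      if (!is.null(queue)) return(length(private$get_queue(queue)))
      sum(vapply(ls(envir = private$queues), function(q) {
        length(base::get(q, envir = private$queues))
      }, integer(1)))
    },
    #' @description Number of outstanding (leased, unacked) messages.
    outstanding = function() length(private$leases),
    #' @description Queued messages of a queue, without leasing them.
    #' @param queue queue name.
    peek = function(queue) private$get_queue(queue)
  ),
  private = list(
    queues = NULL, leases = NULL, clock = 0, lease_n = 0L, journal = NULL,
    get_queue = function(queue) {
      if (!exists(queue, envir = private$queues, inherits = FALSE)) {
        assign(queue, list(), envir = private$queues)
      }
      base::get(queue, envir = private$queues, inherits = FALSE)
    },
    log = function(op, queue, msg) {
      if (is.null(private$journal)) return(invisible(NULL))
      cat(paste(op, queue, msg$doc_id, msg$status, "\n"),
          file = private$journal, append = TRUE)
    }
  )
)

# -- configuration and routing -----------------------------------------------

#' Load and validate a pipeline configuration
#'
#' The YAML file has four sections: `database` (store backend), `mq` (broker
#' parameters), `workflow` (ordered consumer aliases) and `consumers` (alias
#' -> settings with mandatory `class` and `status` fields plus free
#' consumer-specific options).
#'
#' @param path YAML file path, or an already-parsed list.
#' @return a validated `pipeline_config` with its route table attached.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  for (sec in c("database", "mq", "workflow", "consumers")) {
    if (is.null(cfg[[sec]])) stop_parse("config is missing section '", sec, "'")
  }
  aliases <- as.character(unlist(cfg$workflow))
  if (length(aliases) == 0L) stop_parse("workflow is empty")
  statuses <- character(0)
  for (a in aliases) {
    cc <- cfg$consumers[[a]]
    if (is.null(cc)) stop_parse("workflow references undefined consumer '",
                                a, "'")
    if (is.null(cc$class)) stop_parse("consumer '", a, "' has no class")
    if (is.null(cc$status)) stop_parse("consumer '", a, "' has no status")
    statuses <- c(statuses, cc$status)
  }
  if (anyDuplicated(statuses)) {
    stop_parse("duplicate consumer status label: ",
               statuses[duplicated(statuses)][1L])
  }
  cfg$workflow <- aliases
  structure(c(cfg, list(route_table = build_route_table(cfg, aliases))),
            class = "pipeline_config")
}

build_route_table <- function(cfg, aliases) {
  start <- if (!is.null(cfg$mq$start)) cfg$mq$start else "new"
  end <- if (!is.null(cfg$mq$end)) cfg$mq$end else "finished"
  routes <- character(0)
  for (i in seq_along(aliases)) {
    input <- if (i == 1L) start else cfg$consumers[[aliases[i - 1L]]]$status
    routes[[input]] <- paste0("q.", aliases[i])
  }
  routes[[cfg$consumers[[aliases[length(aliases)]]]$status]] <- "__end__"
  list(start = start, end = end, routes = routes)
}

#' Route one status message
#'
#' A known status puts the message on the mapped queue; the terminal route
#' marks the document finished; an unknown status goes to the dead-letter
#' queue (`dlq`) with a warning.
#'
#' @param msg `list(doc_id=, status=)`.
#' @param table route table from [load_config()].
#' @param broker a [Broker].
#' @param store a document store.
#' @return invisibly, the queue routed to (`"__end__"` or `"dlq"`).
#' @export
dispatch <- function(msg, table, broker, store) {
  target <- if (msg$status %in% names(table$routes)) {
    table$routes[[msg$status]]
  } else NULL
  if (is.null(target)) {
    warning("no route for status '", msg$status, "'; dead-lettered",
            call. = FALSE)
    broker$put("dlq", list(doc_id = msg$doc_id, status = msg$status))
    return(invisible("dlq"))
  }
  if (identical(target, "__end__")) {
    store$update_status(msg$doc_id, table$end)
    return(invisible("__end__"))
  }
  broker$put(target, list(doc_id = msg$doc_id, status = msg$status))
  invisible(target)
}

# -- consumer plugins --------------------------------------------------------

#' Consumer plugin registry
#'
#' Maps a `class` identifier from the configuration to a factory
#' `function(options)` returning the plugin lifecycle list:
#' `init(options)`, `process_record(wrapper)` -> updated wrapper, and
#' `shutdown()`. Built-in classes: `jsontl-transform` (applies a JSONTL
#' script to the original record), `toy-enhancer` (annotates the transformed
#' record; exercises the plugin contract) and `file-export` (writes the
#' transformed record to one JSON file per document, idempotently).
#'
#' @param defaults register the built-in classes?
#' @return a registry object.
#' @export
consumer_registry <- function(defaults = TRUE) {
  reg <- structure(list(factories = new.env(parent = emptyenv())),
                   class = "consumer_registry")
  if (defaults) {
    register_consumer(reg, "jsontl-transform", function(options) {
      script <- NULL
      list(
        init = function(opts) {
          txt <- if (!is.null(opts$script)) opts$script else opts$scriptFile
          script <<- parse_script(txt)
        },
        process_record = function(w) {
          w$transformed_record <- execute_script(script, w$original_record)
          w
        },
        shutdown = function() invisible(NULL)
      )
    })
    register_consumer(reg, "toy-enhancer", function(options) {
      seen_options <- NULL
      list(
        init = function(opts) seen_options <<- opts,
        process_record = function(w) {
          tr <- if (!is.null(w$transformed_record)) w$transformed_record
                else w$original_record
          tr[["enhancement"]] <- tree_object(
            enhancer = "toy",
            tag = if (!is.null(seen_options$tag)) seen_options$tag else "none")
          w$transformed_record <- tr
          w
        },
        shutdown = function() invisible(NULL),
        options = function() seen_options
      )
    })
    register_consumer(reg, "file-export", function(options) {
      dir <- NULL
      list(
        init = function(opts) {
          dir <<- opts$dir
          dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        },
        process_record = function(w) {
          fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", w$doc_id),
                                      ".json"))
          tr <- if (!is.null(w$transformed_record)) w$transformed_record
                else w$original_record
          writeLines(tree_to_json(tr), fn)
          w
        },
        shutdown = function() invisible(NULL)
      )
    })
  }
  reg
}

#' Register a consumer plugin class
#'
#' @param registry a [consumer_registry()].
#' @param class_id class identifier used in the configuration.
#' @param factory `function(options)` returning the lifecycle list.
#' @return the registry, invisibly.
#' @export
register_consumer <- function(registry, class_id, factory) {
  if (exists(class_id, envir = registry$factories, inherits = FALSE)) {
    stop_parse("consumer class '", class_id, "' is already registered")
  }
  assign(class_id, factory, envir = registry$factories)
  invisible(registry)
}

make_consumer <- function(registry, class_id, options) {
  if (!exists(class_id, envir = registry$factories, inherits = FALSE)) {
    stop_parse("no plugin registered for consumer class '", class_id, "'")
  }
  factory <- get(class_id, envir = registry$factories, inherits = FALSE)
  inst <- factory(options)
  inst$init(options)
  inst
}

# -- the run loop ------------------------------------------------------------

make_container <- function(config, registry) {
  lanes <- list()
  for (alias in config$workflow) {
    cc <- config$consumers[[alias]]
    lanes[[alias]] <- list(
      alias = alias,
      queue = paste0("q.", alias),
      out_status = cc$status,
      consumer = make_consumer(registry, cc$class, cc)
    )
  }
  lanes
}

#' Run a configured pipeline over a set of sources
#'
#' Ingests every source into the store, then drives the dispatcher and `n`
#' consumer containers (independent execution lanes multiplexed round-robin
#' over a simulated clock) until the broker is quiescent. With `kill_rate >
#' 0`, lanes randomly "crash" after taking a message; the unacked lease
#' expires and the message is redelivered — the final document set must not
#' depend on it.
#'
#' @param config a `pipeline_config` (or path to one).
#' @param sources list of `source_descriptor`s.
#' @param registry consumer plugin registry.
#' @param store document store (defaults per config: `memory`, or `file`
#'   with `database.dir`).
#' @param fetcher a [Fetcher].
#' @param n_containers number of consumer containers.
#' @param kill_rate per-message probability of a simulated consumer crash.
#' @param seed RNG seed for the kill schedule.
#' @param add_container_at optional round number at which one more container
#'   joins the running pipeline.
#' @param max_rounds safety bound on scheduler rounds.
#' @return run report: ingestion totals, per-status counts, broker
#'   accounting, and the conservation indicator.
#' @export
run_pipeline <- function(config, sources, registry = consumer_registry(),
                         store = NULL, fetcher = Fetcher$new(),
                         n_containers = 1L, kill_rate = 0,
                         seed = NULL, add_container_at = NULL,
                         max_rounds = 100000L) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(store)) {
    store <- if (identical(config$database$backend, "file")) {
      FileStore$new(config$database$dir)
    } else MemoryStore$new()
  }
  lease <- if (!is.null(config$mq$lease)) as.integer(config$mq$lease) else 5L
  broker <- Broker$new(lease_ticks = lease, journal = config$mq$journal)
  table <- config$route_table

  containers <- lapply(seq_len(n_containers), function(i) {
    make_container(config, registry)
  })

  ingested <- character(0)
  ingest_reports <- list()
  for (src in sources) {
    rep <- run_ingestion(src, store, fetcher, start_status = table$start)
    ingest_reports[[src$source_id]] <- rep
    ingested <- c(ingested, rep$doc_ids)
    for (id in rep$doc_ids) {
      broker$put("q.dispatch", list(doc_id = id, status = table$start))
    }
  }

  errors <- 0L
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > max_rounds) stop_record("pipeline did not quiesce")
    if (!is.null(add_container_at) && rounds == add_container_at) {
      containers[[length(containers) + 1L]] <- make_container(config, registry)
    }
    repeat {
      m <- broker$take("q.dispatch")
      if (is.null(m)) break
      dispatch(m, table, broker, store)
      broker$ack(m$lease_id)
    }
    for (cont in containers) {
      for (lane in cont) {
        m <- broker$take(lane$queue)
        if (is.null(m)) next
        killed <- kill_rate > 0 && runif(1) < kill_rate
        # a pre-processing crash: lease expires, message redelivered
        if (killed && runif(1) < 0.5) next
        w <- store$get(m$doc_id)
        res <- tryCatch(lane$consumer$process_record(w),
                        error = function(e) e)
        if (inherits(res, "error")) {
          store$put(wrapper_set_status(w, "error"))
          errors <- errors + 1L
        } else {
          store$put(wrapper_set_status(res, lane$out_status))
          # a post-write crash: the store write is idempotent, the unacked
          # message is redelivered and the status message sent on retry
          if (killed) next
          broker$put("q.dispatch",
                     list(doc_id = m$doc_id, status = lane$out_status))
        }
        broker$ack(m$lease_id)
      }
    }
    broker$tick(1)
    if (broker$size() - broker$size("dlq") == 0L &&
        broker$outstanding() == 0L) break
  }

  for (cont in containers) for (lane in cont) lane$consumer$shutdown()

  statuses <- vapply(store$select(), `[[`, character(1), "status")
  per_status <- if (length(statuses)) table(statuses) else table(character(0))
  finished_ids <- vapply(Filter(function(w) identical(w$status, table$end),
                                store$select()), `[[`, character(1), "doc_id")
  list(
    ingested = length(ingested),
    ingest_reports = ingest_reports,
    finished = sum(statuses == table$end),
    errors = errors,
    dlq = broker$size("dlq"),
    per_status = as.list(per_status),
    broker = list(puts = broker$puts, acks = broker$acks,
                  redeliveries = broker$redeliveries,
                  dead_letters = broker$size("dlq")),
    rounds = rounds,
    store = store,
    finished_ids = sort(finished_ids),
    conserved = {
      error_ids <- vapply(Filter(function(w) identical(w$status, "error"),
                                 store$select()),
                          `[[`, character(1), "doc_id")
      dlq_ids <- vapply(broker$peek("dlq"), `[[`, character(1), "doc_id")
      terminal <- c(finished_ids, error_ids, dlq_ids)
      setequal(ingested, terminal) && !anyDuplicated(terminal)
    }
  )
}
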