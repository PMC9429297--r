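# In-code fixtures: tiny event tables and graph constructors.

event_row <- function(kind, message_id, group_id, actor_id, date) {
  data.frame(kind = kind, message_id = message_id, group_id = group_id,
             actor_id = actor_id, date = as.Date(date),
             stringsAsFactors = FALSE)
}

# one POST by `poster` plus VIEW_MARKs by each of `viewers`
post_with_views <- function(msg, group, poster, viewers, date = "2018-06-01") {
  rbind(event_row("POST", msg, group, poster, date),
        if (length(viewers)) {
          do.call(rbind, lapply(viewers, function(v)
            event_row("VIEW_MARK", msg, group, v, date)))
        })
}

write_event_csv <- function(events, path = tempfile(fileext = ".csv")) {
  write.csv(events, path, row.names = FALSE)
  path
}

# named adjacency builders
adj_star <- function(n) { A <- matrix(FALSE, n, n); A[1, 2:n] <- TRUE; A }
adj_path <- function(n) { A <- matrix(FALSE, n, n); A[cbind(1:(n - 1), 2:n)] <- TRUE; A }
adj_cycle <- function(n) { A <- matrix(FALSE, n, n); A[cbind(1:n, c(2:n, 1))] <- TRUE; A }
adj_complete <- function(n) { A <- matrix(TRUE, n, n); diag(A) <- FALSE; A }

# quick network with given node count (path graph), for filter tests
sized_net <- function(n, gid = sprintf("g%d", n)) adj_to_net(adj_path(n), group_id = gid)
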