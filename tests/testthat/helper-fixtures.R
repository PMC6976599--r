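# Small in-code fixtures shared across tests.

make_edges <- function(u, v, cost, layer = "l1",
                       kind_u = "protein", kind_v = "protein") {
  data.frame(u = u, v = v, kind_u = kind_u, kind_v = kind_v,
             confidence = 1 - cost, cost = cost, layer = layer,
             stringsAsFactors = FALSE)
}

make_interactome <- function(u, v, cost, ...) {
  compose_interactome(list(make_edges(u, v, cost, ...)))
}

make_prizes <- function(ids, values, layers = "l1") {
  pt <- data.frame(node_id = ids, prize = values,
                   layers = rep_len(layers, length(ids)),
                   stringsAsFactors = FALSE)
  class(pt) <- c("prize_table", "data.frame")
  pt
}

write_edge_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
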