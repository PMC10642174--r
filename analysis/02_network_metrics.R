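#!/usr/bin/env Rscript
# Descriptive structure of the regulatory network: connection density,
# clustering, and per-node centralities (degree, Wasserman-Faust closeness,
# normalized betweenness, mean outgoing path length). The most central
# mediator is the network's key information broker -- the role substance P
# plays in the text-mined mTBI circuitry.

suppressPackageStartupMessages({
  library(declogic)
  library(jsonlite)
})

net <- read_network("results/study/network.csv",
                    node_table = "results/study/nodes.csv")

glob <- global_metrics(net)
ct <- node_centralities(net)
ct <- ct[order(-ct$betweenness), ]

write.csv(ct, "results/metrics.csv", row.names = FALSE)
write_json(glob, "results/global_metrics.json", auto_unbox = TRUE,
           digits = 6)

cat(sprintf("density %.4f (%.1f%%), clustering %.3f, mean shortest path %.2f\n",
            glob$density, 100 * glob$density, glob$clustering,
            glob$mean_shortest_path))
top <- ct[1, ]
cat(sprintf("top information broker: %s (betweenness %.3f, closeness %.3f, in %d / out %d)\n",
            top$id, top$betweenness, top$closeness, top$indegree,
            top$outdegree))
cat(sprintf("closeness leader: %s\n", ct$id[which.max(ct$closeness)]))
cat("wrote results/metrics.csv and results/global_metrics.json\n")
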