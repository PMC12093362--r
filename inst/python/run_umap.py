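"""UMAP bridge: embed a descriptor CSV (key + numeric columns) to 2-D.

Usage: python run_umap.py IN OUT N_NEIGHBORS MIN_DIST SEED
"""
import sys

import numpy as np
import pandas as pd


def main():
    fin, fout, n_neighbors, min_dist, seed = sys.argv[1:6]
    import umap  # deferred: import is slow

    tab = pd.read_csv(fin)
    keys = tab.iloc[:, 0].astype(str)
    x = tab.iloc[:, 1:].to_numpy(dtype=float)
    reducer = umap.UMAP(
        n_neighbors=int(n_neighbors),
        min_dist=float(min_dist),
        n_components=2,
        random_state=int(seed),
        n_jobs=1,
    )
    emb = reducer.fit_transform(x)
    out = pd.DataFrame({"key": keys, "x": emb[:, 0], "y": emb[:, 1]})
    out.to_csv(fout, index=False)


if __name__ == "__main__":
    main()
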