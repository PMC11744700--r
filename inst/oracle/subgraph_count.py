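#!/usr/bin/env python
"""Independent brute-force substructure-count oracle.

Reads JSON from stdin: {"molecules": [smiles...], "patterns": [smarts...]}.
For every (molecule, pattern) pair, enumerates ALL subgraph isomorphisms of
the pattern into the molecule (uniquify=False, i.e. every atom-order mapping)
with RDKit, then deduplicates the matches by their matched atom-index SET and
counts the distinct sets. Writes a JSON matrix (rows = molecules, columns =
patterns) to stdout. RDKit is an independent codebase from the OpenBabel
matcher under test.
"""
import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def count_distinct(mol, query):
    matches = mol.GetSubstructMatches(query, uniquify=False, maxMatches=1000000)
    return len({frozenset(m) for m in matches})


def main():
    task = json.load(sys.stdin)
    mols = []
    for smi in task["molecules"]:
        m = Chem.MolFromSmiles(smi)
        if m is None:
            raise SystemExit(f"oracle: invalid SMILES {smi!r}")
        mols.append(m)
    queries = []
    for p in task["patterns"]:
        q = Chem.MolFromSmarts(p)
        if q is None:
            raise SystemExit(f"oracle: invalid SMARTS {p!r}")
        queries.append(q)
    out = [[count_distinct(m, q) for q in queries] for m in mols]
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
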