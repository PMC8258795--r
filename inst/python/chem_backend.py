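"""Descriptor backend: Morgan/ECFP bits, Wildman-Crippen logP (with
per-atom contributions) and Ertl TPSA for a batch of SMILES.

Reads a TSV (name<TAB>smiles) and writes one JSON object per run:
{"compounds": [{"name", "smiles", "on_bits", "wlogp", "tpsa",
                "atom_logp": [...]}, ...],
 "errors": [{"name", "smiles"}, ...]}
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, Descriptors, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def main(tsv_path, n_bits, radius, out_path):
    n_bits = int(n_bits)
    radius = int(radius)
    compounds, errors = [], []
    with open(tsv_path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            name, smiles = line.split("\t")[:2]
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                errors.append({"name": name, "smiles": smiles})
                continue
            fp = AllChem.GetMorganFingerprintAsBitVect(
                mol, radius=radius, nBits=n_bits)
            # Per-atom contributions over the H-added molecule: implicit
            # hydrogens carry their own Wildman-Crippen contributions.
            contribs = rdMolDescriptors._CalcCrippenContribs(
                Chem.AddHs(mol))
            compounds.append({
                "name": name,
                "smiles": smiles,
                # 1-based bit indices for R
                "on_bits": [b + 1 for b in fp.GetOnBits()],
                "wlogp": Crippen.MolLogP(mol),
                "tpsa": Descriptors.TPSA(mol),
                "atom_logp": [c[0] for c in contribs],
            })
    with open(out_path, "w") as fh:
        json.dump({"compounds": compounds, "errors": errors}, fh)


if __name__ == "__main__":
    main(*sys.argv[1:5])
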