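"""Knowledge-based distance-geometry conformer embedding.

Reads a tab-separated file with columns: id, smiles, seed.
Writes an SDF (explicit hydrogens) with one embedded conformer per record,
carrying the record id as molecule name and the seed as an SD property.
Records that fail to embed are reported on stdout as "FAIL <id>".

Protocol: ETKDGv3 starting from random coordinates with the given seed;
all other parameters at their defaults.
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem


def embed(smiles, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.useRandomCoords = True
    params.randomSeed = int(seed)
    if AllChem.EmbedMolecule(mol, params) != 0:
        return None
    return mol


def main(infile, outfile):
    writer = Chem.SDWriter(outfile)
    with open(infile) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line.strip():
                continue
            rec_id, smiles, seed = line.split("\t")
            mol = embed(smiles, seed)
            if mol is None:
                print("FAIL %s" % rec_id)
                continue
            mol.SetProp("_Name", rec_id)
            mol.SetProp("seed", str(seed))
            writer.write(mol)
    writer.close()
    print("OK")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
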