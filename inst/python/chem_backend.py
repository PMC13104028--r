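#!/usr/bin/env python
"""Minimal RDKit backend for the dlscreen R package.

Invoked as:  python chem_backend.py MODE IN_CSV OUT_CSV [PATTERNS_CSV]

Modes
-----
fingerprint : IN_CSV has columns id,smiles. Writes id,ok,bits where bits is
              a space-separated list of on-bit indices of the RDKit
              path-based (Daylight-like) hashed fingerprint (2048 bits).
match       : IN_CSV as above; PATTERNS_CSV has columns pattern_id,smarts.
              Writes id,ok,<pattern_id...> boolean substructure match matrix.
              Exits with status 3 before processing records if any SMARTS
              fails to parse (configuration error).
descriptors : IN_CSV as above. Writes id,ok,MW,HBA,HBD,clogP.

Rows whose SMILES fails to parse get ok=0 and empty payload columns.
"""
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def read_records(path):
    with open(path, newline="") as fh:
        return list(csv.DictReader(fh))


def parse_mol(smiles):
    if smiles is None or smiles == "":
        return None
    return Chem.MolFromSmiles(smiles)


def mode_fingerprint(records, out_csv):
    with open(out_csv, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["id", "ok", "bits"])
        for rec in records:
            mol = parse_mol(rec["smiles"])
            if mol is None:
                w.writerow([rec["id"], 0, ""])
            else:
                fp = Chem.RDKFingerprint(mol, fpSize=2048)
                bits = " ".join(str(b) for b in fp.GetOnBits())
                w.writerow([rec["id"], 1, bits])


def mode_match(records, out_csv, patterns_csv):
    pats = read_records(patterns_csv)
    compiled = []
    for p in pats:
        q = Chem.MolFromSmarts(p["smarts"])
        if q is None:
            sys.stderr.write("invalid SMARTS pattern: %s\n" % p["pattern_id"])
            sys.exit(3)
        compiled.append((p["pattern_id"], q))
    with open(out_csv, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["id", "ok"] + [pid for pid, _ in compiled])
        for rec in records:
            mol = parse_mol(rec["smiles"])
            if mol is None:
                w.writerow([rec["id"], 0] + [""] * len(compiled))
            else:
                hits = [int(mol.HasSubstructMatch(q)) for _, q in compiled]
                w.writerow([rec["id"], 1] + hits)


def mode_descriptors(records, out_csv):
    with open(out_csv, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["id", "ok", "MW", "HBA", "HBD", "clogP"])
        for rec in records:
            mol = parse_mol(rec["smiles"])
            if mol is None:
                w.writerow([rec["id"], 0, "", "", "", ""])
            else:
                w.writerow([
                    rec["id"], 1,
                    "%.6g" % Descriptors.MolWt(mol),
                    rdMolDescriptors.CalcNumHBA(mol),
                    rdMolDescriptors.CalcNumHBD(mol),
                    "%.6g" % Crippen.MolLogP(mol),
                ])


def main(argv):
    if len(argv) < 4:
        sys.stderr.write(__doc__)
        return 2
    mode, in_csv, out_csv = argv[1], argv[2], argv[3]
    records = read_records(in_csv)
    if mode == "fingerprint":
        mode_fingerprint(records, out_csv)
    elif mode == "match":
        if len(argv) < 5:
            sys.stderr.write("match mode needs PATTERNS_CSV\n")
            return 2
        mode_match(records, out_csv, argv[4])
    elif mode == "descriptors":
        mode_descriptors(records, out_csv)
    else:
        sys.stderr.write("unknown mode %s\n" % mode)
        return 2
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
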