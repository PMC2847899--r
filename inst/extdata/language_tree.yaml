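# Default dated language tree for the Southwest-China STR panel.
# Node ages are years before present; the linguistic distance between two
# populations is the age of their most recent common ancestor node.
# Only three nodes carry dates (Chinese/Tibeto-Burman split, Mongolic/
# Turkic split, and the root joining everything else); all finer
# structure is collapsed onto its nearest dated ancestor.
age: 50000
within_leaf_age: 0
children:
  - name: SinoTibetan
    age: 7000
    children:
      - name: Chinese
        populations: [HanShandong, HanGansu, HanGuangdong]
      - name: TibetoBurman
        populations: [Drung, Nu, Lisu, Tibetan, Yi, Bai, Pumi, Jinuo,
                      Aini, Naxi, Jingpo]
  - name: Altaic
    age: 8000
    children:
      - name: Mongolic
        populations: [Mongolian, Dongxiang, Tu]
      - name: Turkic
        populations: [Uyghur, Kirgiz, Salar]
  - name: TaiKadai
    populations: [Zhuang, Dai, Li, Mulam, Maonan]
  - name: MonKhmer
    populations: [Deang, Blang, WaCangyuan, WaXimeng]
  - name: Iranian
    populations: [Tajik]
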