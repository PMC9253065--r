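{
  "name": "alvernhe_maze",
  "width": 15,
  "height": 15,
  "rows": ["#######.#######", "#.#.#.#.#.#.#.#", "#.#.#.#.#.#.#.#", "#.#.#.#.#.#.#.#", "#.#.#.#.#.#.#.#", "#.#.#.#.#.#.#.#", "#.#.#.#.#.#.#.#", "...............", "##.#.#.#.#.#.##", "##.#.#.#.#.#.##", "##.#.#.#.#.#.##", "##.#.#.#.#.#.##", "##.#.#.#.#.#.##", "##.#.#.#.#.#.##", "###############"],
  "rewards": [
    {
      "row": 8,
      "col": 1,
      "value": 10
    },
    {
      "row": 8,
      "col": 15,
      "value": 10
    }
  ]
}
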