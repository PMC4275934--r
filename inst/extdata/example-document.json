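{
  "doc_id": "EXAMPLE-1",
  "narrative_text": "Pt underwent drug-eluting stent implantation on 05/01/2006 and antiplatelet therapy was started at the time of the procedure. Late stent thrombosis was identified on 07/14/2006.",
  "events": [
    {
      "id": "EVENTID-1",
      "event_type": "stent_implantation",
      "label": "initial stent implantation",
      "span": [13, 51]
    },
    {
      "id": "EVENTID-2",
      "event_type": "late_stent_thrombosis",
      "label": "late stent thrombosis",
      "span": [131, 152]
    },
    {
      "id": "EVENTID-3",
      "event_type": "antiplatelet_start",
      "label": "antiplatelet therapy started",
      "span": [70, 98]
    }
  ],
  "assertions": [
    {
      "subject": "EVENTID-3",
      "relation": "EQUAL",
      "object": {"event": "EVENTID-1"},
      "asserted": true
    }
  ],
  "timestamps": {
    "EVENTID-1": {"start": "2006-05-01"},
    "EVENTID-2": {"start": "2006-07-14"}
  },
  "durations": {},
  "metadata": {
    "source": "synthetic example in the style of a MAUDE complaint annotation"
  }
}
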