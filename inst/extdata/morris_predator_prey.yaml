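# Morris screening of the predator-prey model: five grid levels,
# ten trajectories, two replications per design point.
model: predator_prey
seed: 1
factors:
  - {name: initialnumberofwolves, min: 10, max: 100}
  - {name: initialnumberofsheep, min: 20, max: 200}
  - {name: wolfgainfromfood, min: 10, max: 40}
  - {name: wolfreproduce, min: 2, max: 10}
  - {name: sheepgainfromfood, min: 2, max: 8}
  - {name: sheepreproduce, min: 2, max: 10}
  - {name: grassregrowthtime, min: 10, max: 60}
method:
  p: 5
  r: 10
  ticks: 200
  replications: 2
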