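category,word
joy,happy
joy,happiness
joy,glad
joy,cheerful
joy,delighted
joy,joy
joy,joyful
joy,fun
joy,smiling
joy,laughing
trust,trust
trust,trusting
trust,faith
trust,faithful
trust,reliable
trust,dependable
trust,loyal
trust,loyalty
fear,fear
fear,fears
fear,afraid
fear,scared
fear,frightened
fear,fearful
fear,dread
fear,spooked
surprise,surprise
surprise,surprised
surprise,surprising
surprise,astonished
surprise,amazed
surprise,startled
surprise,shocked
surprise,unexpected
sadness,sad
sadness,sadness
sadness,unhappy
sadness,depressed
sadness,depressing
sadness,miserable
sadness,crying
sadness,tears
sadness,gloomy
sadness,lonely
disgust,disgust
disgust,disgusted
disgust,disgusting
disgust,gross
disgust,nasty
disgust,revolting
disgust,sickening
disgust,repulsed
disgust,yuck
anger,anger
anger,angry
anger,mad
anger,furious
anger,rage
anger,annoyed
anger,irritated
anger,frustrated
anticipation,anticipation
anticipation,anticipating
anticipation,eager
anticipation,eagerly
anticipation,expectant
anticipation,awaiting
love,love
love,loved
love,loving
love,adore
love,affection
love,caring
love,cherish
love,dear
optimism,hope
optimism,hopeful
optimism,hoping
optimism,optimistic
optimism,optimism
optimism,positive
optimism,confident
optimism,encouraged
submission,submissive
submission,obedient
submission,yielding
submission,compliant
submission,deferential
awe,awe
awe,awesome
awe,awestruck
awe,wonder
awe,marvel
awe,breathtaking
disapproval,disapprove
disapproval,disapproval
disapproval,objection
disapproval,disappointed
disapproval,disappointment
remorse,remorse
remorse,regret
remorse,regretful
remorse,sorry
remorse,guilt
remorse,guilty
remorse,ashamed
remorse,shame
contempt,contempt
contempt,scorn
contempt,disdain
contempt,sneer
contempt,mocking
aggressiveness,aggressive
aggressiveness,aggression
aggressiveness,hostile
aggressiveness,hostility
aggressiveness,combative
anxiety,anxiety
anxiety,anxious
anxiety,nervous
anxiety,worried
anxiety,worry
anxiety,worrying
anxiety,stress
anxiety,stressed
anxiety,uneasy
anxiety,panic
anxiety,overwhelmed
pride,pride
pride,proud
pride,accomplished
pride,accomplishment
pride,achievement
pride,triumphant
pride,triumph
gratitude,gratitude
gratitude,grateful
gratitude,thankful
gratitude,thanks
gratitude,thank
gratitude,appreciate
gratitude,appreciated
gratitude,blessed
terror,terror
terror,terrified
terror,terrifying
terror,horror
terror,horrified
terror,petrified
serenity,serene
serenity,serenity
serenity,calm
serenity,peaceful
serenity,peace
serenity,relaxed
serenity,tranquil
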